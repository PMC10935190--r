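#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats coef cor lm predict rnorm sd var
#' @importFrom utils read.csv write.csv
NULL

#' SpectraSet: multi-instrument NIR spectra on a shared wavelength grid
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"signal"}
#' with wavelengths as rows (features) and scans as columns (samples).
#' \code{rowData} carries the wavelength grid in nm; \code{colData} keys each
#' scan by \code{ear_id}, \code{instrument_id} and \code{replicate}
#' (\code{"averaged"} once replicates have been pooled). The
#' \code{signalDomain} slot records whether values are reflectance fractions
#' in (0, 1] or absorbance (log10 1/R) units.
#'
#' @slot signalDomain character, \code{"reflectance"} or \code{"absorbance"}.
#' @export
setClass("SpectraSet",
  contains = "SummarizedExperiment",
  slots = c(signalDomain = "character")
)

setValidity("SpectraSet", function(object) {
  msg <- character()
  if (!"signal" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'signal' is required")
  if (length(object@signalDomain) != 1L ||
      !object@signalDomain %in% c("reflectance", "absorbance"))
    msg <- c(msg, "signalDomain must be 'reflectance' or 'absorbance'")
  rd <- SummarizedExperiment::rowData(object)
  if (!"wavelength" %in% colnames(rd)) {
    msg <- c(msg, "rowData must contain a 'wavelength' column")
  } else {
    wl <- rd$wavelength
    if (anyNA(wl) || is.unsorted(wl, strictly = TRUE))
      msg <- c(msg, "wavelength grid must be strictly increasing")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("ear_id", "instrument_id", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData lacks:", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' InstrumentProfile: simulated spectrometer signature
#'
#' Captures the systematic differences between nominally identical handheld
#' spectrometers: a wavelength registration shift, a photometric gain, an
#' absorbance baseline offset, and the per-scan noise level.
#'
#' @slot instrument_id character label.
#' @slot wavelength_shift nm; positive means the instrument samples the scene
#'   at longer wavelengths than its nominal grid reports.
#' @slot gain dimensionless multiplier on absorbance (> 0).
#' @slot baseline_offset absorbance units added after gain.
#' @slot noise_sd per-scan Gaussian noise SD in absorbance units (>= 0).
#' @export
setClass("InstrumentProfile", slots = c(
  instrument_id = "character",
  wavelength_shift = "numeric",
  gain = "numeric",
  baseline_offset = "numeric",
  noise_sd = "numeric"
))

setValidity("InstrumentProfile", function(object) {
  msg <- character()
  if (length(object@instrument_id) != 1L || !nzchar(object@instrument_id))
    msg <- c(msg, "instrument_id must be a non-empty string")
  if (!isTRUE(object@gain > 0)) msg <- c(msg, "gain must be > 0")
  if (!isTRUE(object@noise_sd >= 0)) msg <- c(msg, "noise_sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SeasonConfig: one growing season of reference moisture data
#'
#' Parameters of the truncated-normal whole-plant moisture distribution,
#' the scatter of ear moisture about the quadratic ear/whole-plant curve,
#' the oven reference error (SEL), and the scan replication design.
#'
#' @slot label season label, e.g. "2021".
#' @slot n_plants number of plants (ears) sampled.
#' @slot wp_mean,wp_sd whole-plant moisture mean and SD, \%w.b.
#' @slot wp_min,wp_max truncation bounds for whole-plant moisture, \%w.b.
#' @slot em_residual_sd SD of ear moisture about the quadratic curve,
#'   percentage points.
#' @slot sel standard error of the oven-drying laboratory reference,
#'   percentage points.
#' @slot n_replicates scans per ear per instrument.
#' @export
setClass("SeasonConfig", slots = c(
  label = "character",
  n_plants = "integer",
  wp_mean = "numeric", wp_sd = "numeric",
  wp_min = "numeric", wp_max = "numeric",
  em_residual_sd = "numeric",
  sel = "numeric",
  n_replicates = "integer"
))

setValidity("SeasonConfig", function(object) {
  msg <- character()
  if (!isTRUE(object@wp_min < object@wp_max))
    msg <- c(msg, "wp_min must be < wp_max")
  if (!isTRUE(object@wp_sd >= 0) || !isTRUE(object@em_residual_sd >= 0) ||
      !isTRUE(object@sel >= 0))
    msg <- c(msg, "all SDs must be >= 0")
  if (!isTRUE(object@n_plants >= 1L)) msg <- c(msg, "n_plants must be >= 1")
  if (!isTRUE(object@n_replicates >= 1L))
    msg <- c(msg, "n_replicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SpectralSceneConfig: the synthetic absorbance scene
#'
#' Gaussian water and dry-matter absorption bands plus a linear baseline and
#' per-sample multiplicative/additive scatter. Absorbance at wavelength w for
#' ear moisture em (\%w.b.) is
#' baseline(w) + (em/100) * sum(water bands) + (1 - em/100) * sum(dry bands),
#' so with noise and scatter off it is exactly affine in em.
#'
#' @slot water_centers,water_widths,water_amplitudes water-band Gaussians
#'   (center nm, SD nm, peak absorbance).
#' @slot dry_centers,dry_widths,dry_amplitudes dry-matter band Gaussians.
#' @slot baseline_intercept,baseline_slope absorbance baseline a + b*(w-1350).
#' @slot scatter_mult_sd,scatter_add_sd SDs of the per-sample multiplicative
#'   (lognormal-ish, applied as 1 + e) and additive scatter terms.
#' @export
setClass("SpectralSceneConfig", slots = c(
  water_centers = "numeric", water_widths = "numeric",
  water_amplitudes = "numeric",
  dry_centers = "numeric", dry_widths = "numeric",
  dry_amplitudes = "numeric",
  baseline_intercept = "numeric", baseline_slope = "numeric",
  scatter_mult_sd = "numeric", scatter_add_sd = "numeric"
))

setValidity("SpectralSceneConfig", function(object) {
  msg <- character()
  if (length(object@water_centers) != length(object@water_widths) ||
      length(object@water_centers) != length(object@water_amplitudes))
    msg <- c(msg, "water band vectors must have equal length")
  if (length(object@dry_centers) != length(object@dry_widths) ||
      length(object@dry_centers) != length(object@dry_amplitudes))
    msg <- c(msg, "dry band vectors must have equal length")
  if (any(object@water_widths <= 0) || any(object@dry_widths <= 0))
    msg <- c(msg, "band widths must be > 0")
  if (length(msg)) msg else TRUE
})

#' PreprocessSpec: one spectral pretreatment
#'
#' One of the candidate pretreatments surveyed before PLS calibration:
#' \code{none}, \code{autoscale}, \code{mean_center}, \code{msc}
#' (multiplicative scatter correction against the mean calibration spectrum),
#' or \code{sg_derivative} (Savitzky-Golay derivative in variable-index
#' space). The shorthand \code{"D-2,2,11"} denotes derivative order 2,
#' polynomial order 2, window 11.
#'
#' @slot method character, one of the five methods above.
#' @slot derivative_order 1 or 2 (sg_derivative only).
#' @slot window odd filter length in variables (sg_derivative only).
#' @slot poly_order 2 or 3 (sg_derivative only).
#' @export
setClass("PreprocessSpec", slots = c(
  method = "character",
  derivative_order = "integer",
  window = "integer",
  poly_order = "integer"
))

setValidity("PreprocessSpec", function(object) {
  msg <- character()
  ok <- c("none", "autoscale", "mean_center", "msc", "sg_derivative")
  if (length(object@method) != 1L || !object@method %in% ok)
    msg <- c(msg, paste("method must be one of:", paste(ok, collapse = ", ")))
  if (identical(object@method, "sg_derivative")) {
    w <- object@window; p <- object@poly_order; d <- object@derivative_order
    if (w %% 2L == 0L) msg <- c(msg, "window must be odd")
    if (!isTRUE(w > p)) msg <- c(msg, "window must exceed poly_order")
    if (!isTRUE(d <= p)) msg <- c(msg, "derivative_order must be <= poly_order")
    if (!d %in% 0:2) msg <- c(msg, "derivative_order must be 0, 1 or 2")
    if (!p %in% 2:3) msg <- c(msg, "poly_order must be 2 or 3")
  }
  if (length(msg)) msg else TRUE
})

#' PLSModel: a fitted PLS calibration
#'
#' Stores the frozen pretreatment state, centering vectors, NIPALS weights
#' and loadings, regression vectors for every latent-variable count up to
#' \code{maxLV}, the chosen number of latent variables, per-LV calibration
#' and cross-validation error curves, the wavelength grid fingerprint and
#' training provenance.
#'
#' @slot pretreatment fitted pretreatment (list with frozen statistics).
#' @slot xMean,yMean centering vectors learned on the (pretreated) training
#'   matrix and response.
#' @slot weights,loadings,yloadings NIPALS W, P (columns per LV) and q.
#' @slot coefficients matrix, column k = regression vector using k LVs.
#' @slot nLV chosen number of latent variables.
#' @slot maxLV number of latent variables actually fitted.
#' @slot grid wavelength grid (nm) the model expects.
#' @slot rmsec,rmsecv,r2cv per-LV error curves (length maxLV).
#' @slot cvPredictions pooled held-out predictions, one column per LV.
#' @slot trainingInfo list: instrument ids, season label, row count, target.
#' @export
setClass("PLSModel", slots = c(
  pretreatment = "list",
  xMean = "numeric", yMean = "numeric",
  weights = "matrix", loadings = "matrix", yloadings = "numeric",
  coefficients = "matrix",
  nLV = "integer", maxLV = "integer",
  grid = "numeric",
  rmsec = "numeric", rmsecv = "numeric", r2cv = "numeric",
  cvPredictions = "matrix",
  trainingInfo = "list"
))

setValidity("PLSModel", function(object) {
  msg <- character()
  if (nrow(object@coefficients) != length(object@grid))
    msg <- c(msg, "regression vector length must equal grid length")
  if (!isTRUE(object@nLV >= 1L) || !isTRUE(object@nLV <= object@maxLV))
    msg <- c(msg, "nLV must be in [1, maxLV]")
  if (length(msg)) msg else TRUE
})

#' CVScheme: Venetian-blinds cross-validation layout
#'
#' Row i (1-based) is assigned to split ((i - 1) \%/\% thickness) \%\%
#' n_splits + 1, the chemometric "Venetian blinds" scheme.
#'
#' @slot method only "venetian_blinds" is implemented.
#' @slot n_splits number of blinds (folds), >= 2.
#' @slot thickness consecutive rows per blind slat, >= 1.
#' @export
setClass("CVScheme", slots = c(
  method = "character", n_splits = "integer", thickness = "integer"
))

setValidity("CVScheme", function(object) {
  msg <- character()
  if (!identical(object@method, "venetian_blinds"))
    msg <- c(msg, "method must be 'venetian_blinds'")
  if (!isTRUE(object@n_splits >= 2L)) msg <- c(msg, "n_splits must be >= 2")
  if (!isTRUE(object@thickness >= 1L)) msg <- c(msg, "thickness must be >= 1")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: calibration/validation statistics for one prediction set
#'
#' @slot n number of (predicted, reference) pairs.
#' @slot rmse root mean square error (divisor N), percentage points.
#' @slot bias mean of predicted - reference.
#' @slot sep bias-corrected residual SD (divisor N - 1); the "standard error
#'   of prediction" when applied to validation residuals.
#' @slot slope,intercept OLS line of predicted on reference.
#' @slot r2 squared Pearson correlation of predicted and reference.
#' @slot rpd_r2 1 / sqrt(1 - R^2), the form used for classification.
#' @slot rpd_sd reference SD / SEP.
#' @slot rpd_class performance class label.
#' @export
setClass("EvaluationReport", slots = c(
  n = "integer", rmse = "numeric", bias = "numeric", sep = "numeric",
  slope = "numeric", intercept = "numeric", r2 = "numeric",
  rpd_r2 = "numeric", rpd_sd = "numeric", rpd_class = "character"
))

#' MethodResult: one whole-plant moisture estimation method's outcome
#'
#' @slot method label: method1_oven_chain, method2_nirs_chain or
#'   method3_direct.
#' @slot predictions data.frame with ear_id, predicted ear moisture (NA for
#'   the direct method), predicted whole-plant moisture and a status column.
#' @slot report \linkS4class{EvaluationReport} against reference whole-plant
#'   moisture over the ears with status "ok".
#' @export
setClass("MethodResult", slots = c(
  method = "character",
  predictions = "data.frame",
  report = "EvaluationReport"
))

#' TransferReport: the instrument-subset calibration/validation matrix
#'
#' @slot calibration data.frame, one row per calibration subset: SEC, R2C,
#'   SECV, R2CV, chosen number of latent variables.
#' @slot validation data.frame, one row per (subset, target) cell with the
#'   validation statistics.
#' @slot models named list of fitted \linkS4class{PLSModel}s per subset.
#' @export
setClass("TransferReport", slots = c(
  calibration = "data.frame",
  validation = "data.frame",
  models = "list"
))
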