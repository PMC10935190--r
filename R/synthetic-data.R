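#' Variable-step wavelength grid
#'
#' Builds a strictly increasing grid whose consecutive steps grow linearly
#' from \code{step_start} at \code{start_nm} toward \code{step_end} at
#' \code{end_nm}, emulating the variable sampling density of compact
#' FT-NIR spectrometers (2.5 nm at 1350 nm widening to 8.8 nm at 2550 nm).
#'
#' @param start_nm,end_nm grid limits in nm, start < end
#' @param step_start,step_end first and asymptotic step sizes in nm
#' @return numeric vector starting at start_nm, never exceeding end_nm
#' @examples
#' g <- makeWavelengthGrid()   # ~213 points over 1350-2550 nm
#' diff(g)[1]                  # 2.5
#' @export
makeWavelengthGrid <- function(start_nm = 1350, end_nm = 2550,
                               step_start = 2.5, step_end = 8.8) {
  if (!(start_nm < end_nm)) stop("start_nm must be < end_nm")
  if (!(step_start > 0 && step_end >= step_start))
    stop("steps must satisfy 0 < step_start <= step_end")
  span <- end_nm - start_nm
  # number of steps whose sizes grow linearly (in step index) from
  # step_start to step_end while their sum stays within the span
  K <- floor(2 * span / (step_start + step_end) + 1e-9)
  if (K < 1L) return(start_nm)
  steps <- if (K == 1L) step_start else
    step_start + (step_end - step_start) * (seq_len(K) - 1) / (K - 1)
  start_nm + c(0, cumsum(steps))
}

#' Season configuration constructor
#'
#' @param label season label
#' @param n_plants number of ears sampled
#' @param wp_mean,wp_sd,wp_min,wp_max truncated-normal parameters of
#'   whole-plant moisture, \%w.b.
#' @param em_residual_sd SD of ear moisture about the quadratic
#'   ear/whole-plant curve, percentage points
#' @param sel oven reference error SD, percentage points
#' @param n_replicates scans per ear per instrument
#' @return a \linkS4class{SeasonConfig}
#' @export
seasonConfig <- function(label, n_plants, wp_mean, wp_sd, wp_min, wp_max,
                         em_residual_sd = 3.2, sel = 0.35,
                         n_replicates = 3L) {
  methods::new("SeasonConfig", label = as.character(label),
               n_plants = as.integer(n_plants),
               wp_mean = wp_mean, wp_sd = wp_sd,
               wp_min = wp_min, wp_max = wp_max,
               em_residual_sd = em_residual_sd, sel = sel,
               n_replicates = as.integer(n_replicates))
}

#' Calibration-season preset (610 ears)
#'
#' Whole-plant moisture mean 63.5, SD 7.3, truncated to [42, 79] \%w.b.
#' Through the quadratic curve this yields ear moistures averaging about
#' 49 \%w.b. with SD about 9.6 and range roughly 34-75; the residual SD of
#' 3.2 reproduces an ear/whole-plant coefficient of determination near 0.89.
#' @export
season2021 <- function() {
  seasonConfig("2021", 610L, wp_mean = 63.5, wp_sd = 7.3,
               wp_min = 42, wp_max = 79)
}

#' Validation-season preset (330 ears)
#'
#' Whole-plant moisture mean 67.7, SD 6.4, truncated to [55, 81] \%w.b.,
#' giving ear moistures averaging about 55 \%w.b. with SD about 10.
#' @export
season2022 <- function() {
  seasonConfig("2022", 330L, wp_mean = 67.7, wp_sd = 6.4,
               wp_min = 55, wp_max = 81)
}

#' Instrument profile constructor
#' @param instrument_id label
#' @param wavelength_shift nm registration shift
#' @param gain absorbance gain (> 0)
#' @param baseline_offset absorbance offset
#' @param noise_sd per-scan absorbance noise SD (>= 0)
#' @return an \linkS4class{InstrumentProfile}
#' @export
instrumentProfile <- function(instrument_id, wavelength_shift = 0,
                              gain = 1, baseline_offset = 0,
                              noise_sd = 0.005) {
  methods::new("InstrumentProfile",
               instrument_id = as.character(instrument_id),
               wavelength_shift = wavelength_shift, gain = gain,
               baseline_offset = baseline_offset, noise_sd = noise_sd)
}

#' Default three-instrument fleet
#'
#' Instruments 1 and 2 are nominal; instrument 3 carries a +3 nm wavelength
#' registration shift and a 3\% photometric gain, enough to induce a
#' cross-instrument prediction bias when it is excluded from calibration.
#' @export
defaultInstrumentProfiles <- function() {
  list(instrumentProfile("1"),
       instrumentProfile("2"),
       instrumentProfile("3", wavelength_shift = 3, gain = 1.03))
}

#' Scene configuration constructor
#' @param water_centers,water_widths,water_amplitudes water band Gaussians
#' @param dry_centers,dry_widths,dry_amplitudes dry-matter band Gaussians
#' @param baseline_intercept,baseline_slope absorbance baseline
#'   a + b * (w - 1350)
#' @param scatter_mult_sd,scatter_add_sd per-sample scatter SDs
#' @return a \linkS4class{SpectralSceneConfig}
#' @export
sceneConfig <- function(water_centers = c(1450, 1950),
                        water_widths = c(60, 80),
                        water_amplitudes = c(0.6, 1.0),
                        dry_centers = c(1730, 2100, 2270),
                        dry_widths = c(50, 70, 60),
                        dry_amplitudes = c(0.25, 0.45, 0.35),
                        baseline_intercept = 0.25,
                        baseline_slope = 1e-4,
                        scatter_mult_sd = 0.05,
                        scatter_add_sd = 0.02) {
  methods::new("SpectralSceneConfig",
    water_centers = water_centers, water_widths = water_widths,
    water_amplitudes = water_amplitudes,
    dry_centers = dry_centers, dry_widths = dry_widths,
    dry_amplitudes = dry_amplitudes,
    baseline_intercept = baseline_intercept,
    baseline_slope = baseline_slope,
    scatter_mult_sd = scatter_mult_sd, scatter_add_sd = scatter_add_sd)
}

#' Default spectral scene
#'
#' Water O-H combination/overtone bands at 1450 and 1950 nm and dry-matter
#' (C-H, starch) bands at 1730, 2100 and 2270 nm over a gently sloping
#' baseline. Band parameters are free parameters of the simulator, chosen
#' to give realistic-looking ear absorbance spectra.
#' @export
defaultScene <- function() sceneConfig()

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(max(n - length(out), 16L) * 2L, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Sample one season of paired moisture references
#'
#' Whole-plant moisture is drawn from a truncated normal; true ear moisture
#' follows the quadratic curve plus residual scatter; oven references add
#' laboratory error (SEL) to both.
#'
#' @param cfg a \linkS4class{SeasonConfig}
#' @param seed optional integer; when given the draw is reproducible
#' @return data.frame(plant_id, wp_true, em_true, em_oven, wp_oven, season)
#' @export
sampleSeason <- function(cfg, seed = NULL) {
  stopifnot(methods::is(cfg, "SeasonConfig"))
  methods::validObject(cfg)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg@n_plants
  wp <- rtruncnorm1(n, cfg@wp_mean, cfg@wp_sd, cfg@wp_min, cfg@wp_max)
  em <- earFromWholeplant(wp) + rnorm(n, 0, cfg@em_residual_sd)
  data.frame(
    plant_id = sprintf("%s_%04d", cfg@label, seq_len(n)),
    wp_true = wp,
    em_true = em,
    em_oven = em + rnorm(n, 0, cfg@sel),
    wp_oven = wp + rnorm(n, 0, cfg@sel),
    season = cfg@label,
    stringsAsFactors = FALSE
  )
}

# baseline, summed water-band and summed dry-band absorbance at wl
scene_components <- function(scene, wl) {
  gauss <- function(centers, widths, amps) {
    a <- numeric(length(wl))
    for (k in seq_along(centers))
      a <- a + amps[k] * exp(-0.5 * ((wl - centers[k]) / widths[k])^2)
    a
  }
  list(base = scene@baseline_intercept +
         scene@baseline_slope * (wl - 1350),
       water = gauss(scene@water_centers, scene@water_widths,
                     scene@water_amplitudes),
       dry = gauss(scene@dry_centers, scene@dry_widths,
                   scene@dry_amplitudes))
}

scene_absorbance <- function(em, scene, wl) {
  cmp <- scene_components(scene, wl)
  cmp$base + (em / 100) * cmp$water + (1 - em / 100) * cmp$dry
}

#' Render one reflectance spectrum
#'
#' Absorbance is built as baseline + (em/100) * water bands +
#' (1 - em/100) * dry-matter bands, evaluated at the instrument's shifted
#' wavelengths, distorted by the per-sample multiplicative/additive scatter,
#' scaled by the instrument gain, offset, and perturbed by Gaussian noise
#' (drawn from the current RNG state when noise_sd > 0). Returned as
#' reflectance R = 10^(-A), floored at 1e-6 and capped at 1.
#'
#' @param em ear moisture, \%w.b., strictly inside (0, 100)
#' @param scene a \linkS4class{SpectralSceneConfig}
#' @param profile an \linkS4class{InstrumentProfile}
#' @param grid wavelength grid in nm
#' @param scatter_mult,scatter_add per-sample scatter realization (defaults:
#'   none); campaigns draw these once per (ear, instrument) so replicate
#'   scans differ only by instrument noise
#' @return reflectance vector in (0, 1], aligned to grid
#' @export
renderSpectrum <- function(em, scene, profile = instrumentProfile("1"),
                           grid = makeWavelengthGrid(),
                           scatter_mult = 1, scatter_add = 0) {
  if (!(em > 0 && em < 100))
    stop("ear moisture must be strictly inside (0, 100) %w.b.")
  wl_eff <- grid + profile@wavelength_shift
  a <- scene_absorbance(em, scene, wl_eff)
  a <- a * scatter_mult + scatter_add
  a <- a * profile@gain + profile@baseline_offset
  if (profile@noise_sd > 0) a <- a + rnorm(length(a), 0, profile@noise_sd)
  r <- 10^(-pmax(a, 0))
  pmin(pmax(r, 1e-6), 1)
}

#' Simulate a multi-season, multi-instrument scanning campaign
#'
#' One scan row per (ear, instrument, replicate): the per-sample scatter is
#' drawn once per (ear, instrument) so replicate scans differ only by
#' instrument noise. All randomness is governed by \code{seed} through
#' stage-keyed derived seeds, so the campaign is reproducible end to end.
#'
#' @param seasons list of \linkS4class{SeasonConfig}s
#' @param profiles list of \linkS4class{InstrumentProfile}s with unique ids
#' @param scene a \linkS4class{SpectralSceneConfig}
#' @param seed integer master seed
#' @param grid wavelength grid in nm
#' @return list(spectra = reflectance \linkS4class{SpectraSet},
#'   reference = data.frame(ear_id, ear_moisture_wb, wholeplant_moisture_wb,
#'   season) using oven values, truth = the full \code{\link{sampleSeason}}
#'   table)
#' @export
simulateCampaign <- function(seasons, profiles = defaultInstrumentProfiles(),
                             scene = defaultScene(), seed = 1L,
                             grid = makeWavelengthGrid()) {
  if (length(seasons) < 1L) stop("at least one season is required")
  if (length(profiles) < 1L) stop("at least one instrument is required")
  if (methods::is(seasons, "SeasonConfig")) seasons <- list(seasons)
  ids <- vapply(profiles, function(p) p@instrument_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate instrument ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  truth <- do.call(rbind, lapply(seasons, function(cfg) {
    sampleSeason(cfg, seed = deriveSeed(seed, paste0("season:", cfg@label)))
  }))
  n_rep <- vapply(seasons, function(cfg) cfg@n_replicates, integer(1))
  rep_of <- rep(n_rep, vapply(seasons, function(cfg) cfg@n_plants,
                              integer(1)))
  total <- sum(rep_of) * length(profiles)
  sig <- matrix(NA_real_, nrow = total, ncol = length(grid))
  info <- data.frame(ear_id = character(total),
                     instrument_id = character(total),
                     replicate = character(total),
                     stringsAsFactors = FALSE)
  row <- 0L
  npt <- length(grid)
  for (p in profiles) {
    set.seed(deriveSeed(seed, paste0("scans:", p@instrument_id)))
    cmp <- scene_components(scene, grid + p@wavelength_shift)
    for (i in seq_len(nrow(truth))) {
      s_mult <- 1 + rnorm(1, 0, scene@scatter_mult_sd)
      s_add <- rnorm(1, 0, scene@scatter_add_sd)
      em <- truth$em_true[i]
      # deterministic per-(ear, instrument) absorbance; replicate scans
      # below differ only by instrument noise
      a0 <- cmp$base + (em / 100) * cmp$water + (1 - em / 100) * cmp$dry
      a0 <- (a0 * s_mult + s_add) * p@gain + p@baseline_offset
      for (r in seq_len(rep_of[i])) {
        row <- row + 1L
        a <- if (p@noise_sd > 0) a0 + rnorm(npt, 0, p@noise_sd) else a0
        sig[row, ] <- pmin(pmax(10^(-pmax(a, 0)), 1e-6), 1)
        info$ear_id[row] <- truth$plant_id[i]
        info$instrument_id[row] <- p@instrument_id
        info$replicate[row] <- as.character(r)
      }
    }
  }
  list(
    spectra = SpectraSet(sig, grid, info, domain = "reflectance"),
    reference = data.frame(ear_id = truth$plant_id,
                           ear_moisture_wb = truth$em_oven,
                           wholeplant_moisture_wb = truth$wp_oven,
                           season = truth$season,
                           stringsAsFactors = FALSE),
    truth = truth
  )
}
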