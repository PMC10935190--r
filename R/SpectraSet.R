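#' Construct a SpectraSet
#'
#' @param signal numeric matrix of spectra, one row per scan and one column
#'   per wavelength (the chemometric orientation; stored transposed so
#'   wavelengths are features).
#' @param wavelength numeric, strictly increasing wavelength grid in nm,
#'   length = ncol(signal).
#' @param scanInfo data.frame with columns ear_id, instrument_id, replicate
#'   (one row per scan).
#' @param domain "reflectance" (default) or "absorbance".
#' @return a \linkS4class{SpectraSet}
#' @examples
#' s <- SpectraSet(matrix(0.5, 2, 3), c(1400, 1500, 1600),
#'                 data.frame(ear_id = c("a", "a"), instrument_id = "1",
#'                            replicate = c("1", "2")))
#' wavelengths(s)
#' @export
SpectraSet <- function(signal, wavelength, scanInfo,
                       domain = c("reflectance", "absorbance")) {
  domain <- match.arg(domain)
  signal <- as.matrix(signal)
  if (ncol(signal) != length(wavelength))
    stop("ncol(signal) must equal length(wavelength)")
  if (nrow(signal) != nrow(scanInfo))
    stop("nrow(signal) must equal nrow(scanInfo)")
  scanInfo$ear_id <- as.character(scanInfo$ear_id)
  scanInfo$instrument_id <- as.character(scanInfo$instrument_id)
  scanInfo$replicate <- as.character(scanInfo$replicate)
  a <- t(signal)
  dimnames(a) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = a),
    rowData = S4Vectors::DataFrame(wavelength = as.numeric(wavelength)),
    colData = S4Vectors::DataFrame(scanInfo)
  )
  methods::new("SpectraSet", se, signalDomain = domain)
}

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectraSet", function(x) {
  as.numeric(SummarizedExperiment::rowData(x)$wavelength)
})

#' @rdname signalDomain
#' @export
setMethod("signalDomain", "SpectraSet", function(x) x@signalDomain)

#' @rdname scanInfo
#' @export
setMethod("scanInfo", "SpectraSet", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "SpectraSet", function(x) {
  m <- t(SummarizedExperiment::assay(x, "signal"))
  colnames(m) <- format_wavelength(wavelengths(x))
  rownames(m) <- NULL
  m
})

setMethod("show", "SpectraSet", function(object) {
  wl <- wavelengths(object)
  info <- scanInfo(object)
  cat("SpectraSet:", ncol(object), "scans,", length(wl),
      "wavelengths (", min(wl), "-", max(wl), "nm ),",
      object@signalDomain, "domain\n")
  cat("  ears:", length(unique(info$ear_id)),
      " instruments:", paste(sort(unique(info$instrument_id)),
                             collapse = ", "), "\n")
})

#' @rdname toAbsorbance
#' @export
setMethod("toAbsorbance", "SpectraSet", function(x) {
  if (x@signalDomain != "reflectance")
    stop("toAbsorbance expects a reflectance-domain SpectraSet")
  a <- SummarizedExperiment::assay(x, "signal")
  if (any(a <= 0))
    stop("reflectance values must be > 0 to convert to absorbance")
  SummarizedExperiment::assay(x, "signal") <- log10(1 / a)
  x@signalDomain <- "absorbance"
  methods::validObject(x)
  x
})

#' @rdname averageReplicates
#' @export
setMethod("averageReplicates", "SpectraSet", function(x, by) {
  by <- match.arg(by, c("ear_instrument", "ear"))
  info <- scanInfo(x)
  if (nrow(info) == 0L) stop("cannot average an empty SpectraSet")
  key <- if (by == "ear_instrument") {
    paste(info$ear_id, info$instrument_id, sep = "\r")
  } else {
    info$ear_id
  }
  groups <- split(seq_len(nrow(info)), factor(key, levels = unique(key)))
  a <- SummarizedExperiment::assay(x, "signal")
  avg <- vapply(groups, function(idx) rowMeans(a[, idx, drop = FALSE]),
                numeric(nrow(a)))
  first <- vapply(groups, `[`, integer(1), 1L)
  out_info <- data.frame(
    ear_id = info$ear_id[first],
    instrument_id = if (by == "ear_instrument")
      info$instrument_id[first] else "all",
    replicate = "averaged",
    stringsAsFactors = FALSE
  )
  SpectraSet(t(avg), wavelengths(x), out_info, domain = x@signalDomain)
})

#' Subset a SpectraSet to the scans of given instruments
#' @param x a \linkS4class{SpectraSet}
#' @param instruments character vector of instrument ids
#' @export
filterInstruments <- function(x, instruments) {
  keep <- scanInfo(x)$instrument_id %in% as.character(instruments)
  if (!any(keep))
    stop("no scans for instrument(s): ",
         paste(instruments, collapse = ", "))
  x[, keep]
}

format_wavelength <- function(wl) sprintf("%.1f", wl)
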