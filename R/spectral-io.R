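#' Write spectra to CSV
#'
#' Columns: ear_id, instrument_id, replicate, then one column per
#' wavelength, headed by the wavelength in nm with one decimal. UTF-8,
#' comma-separated, '.' decimal. Only reflectance-domain sets are written,
#' so files round-trip through \code{\link{readSpectra}}.
#'
#' @param x a \linkS4class{SpectraSet}
#' @param path output file
#' @export
writeSpectra <- function(x, path) {
  stopifnot(methods::is(x, "SpectraSet"))
  m <- spectraMatrix(x)
  df <- cbind(scanInfo(x)[, c("ear_id", "instrument_id", "replicate")],
              as.data.frame(m, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spectra from CSV
#'
#' Parses the dialect written by \code{\link{writeSpectra}}: the wavelength
#' grid is recovered from the numeric header columns and must be strictly
#' increasing; all spectral cells must be numeric. Errors name the offending
#' row or column.
#'
#' @param path CSV file
#' @param domain signal domain of the stored values (default reflectance)
#' @return a \linkS4class{SpectraSet}
#' @export
readSpectra <- function(path, domain = "reflectance") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  key_cols <- c("ear_id", "instrument_id", "replicate")
  miss <- setdiff(key_cols, names(df))
  if (length(miss))
    stop("spectra file lacks key column(s): ", paste(miss, collapse = ", "))
  wl_names <- setdiff(names(df), key_cols)
  wl <- suppressWarnings(as.numeric(wl_names))
  if (anyNA(wl))
    stop("non-numeric wavelength header column(s): ",
         paste(wl_names[is.na(wl)], collapse = ", "))
  if (is.unsorted(wl, strictly = TRUE))
    stop("wavelength header must be strictly increasing")
  m <- as.matrix(df[, wl_names, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[wl_names], is.numeric, logical(1)))
    stop("non-numeric spectral values in column(s): ",
         paste(wl_names[bad], collapse = ", "))
  }
  if (anyNA(m)) {
    bad_row <- which(rowSums(is.na(m)) > 0)[1L]
    stop("missing/non-numeric spectral value in row ", bad_row)
  }
  SpectraSet(m, wl, df[, key_cols], domain = domain)
}

#' Write a reference moisture table to CSV
#' @param reference data.frame with ear_id, ear_moisture_wb,
#'   wholeplant_moisture_wb, season
#' @param path output file
#' @export
writeReference <- function(reference, path) {
  need <- c("ear_id", "ear_moisture_wb", "wholeplant_moisture_wb", "season")
  miss <- setdiff(need, names(reference))
  if (length(miss))
    stop("reference table lacks: ", paste(miss, collapse = ", "))
  write.csv(reference[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference moisture table from CSV
#' @param path CSV file written by \code{\link{writeReference}}
#' @export
readReference <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(ear_id = "character", season = "character"))
  need <- c("ear_id", "ear_moisture_wb", "wholeplant_moisture_wb", "season")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reference file lacks: ", paste(miss, collapse = ", "))
  df
}
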