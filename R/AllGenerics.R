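#' Wavelength grid of a SpectraSet
#' @param x a \linkS4class{SpectraSet}
#' @return numeric vector of wavelengths in nm, strictly increasing
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Signal domain ("reflectance" or "absorbance")
#' @param x a \linkS4class{SpectraSet}
#' @export
setGeneric("signalDomain", function(x) standardGeneric("signalDomain"))

#' Scan key table (ear_id, instrument_id, replicate)
#' @param x a \linkS4class{SpectraSet}
#' @return a data.frame with one row per scan
#' @export
setGeneric("scanInfo", function(x) standardGeneric("scanInfo"))

#' Spectra as a scans-by-wavelengths matrix
#'
#' The chemometric orientation: one row per scan, one column per wavelength
#' (columns named by wavelength). This is the matrix handed to pretreatments
#' and PLS.
#' @param x a \linkS4class{SpectraSet}
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' Convert reflectance spectra to absorbance (log10 1/R)
#' @param x a \linkS4class{SpectraSet} in the reflectance domain
#' @return a \linkS4class{SpectraSet} in the absorbance domain
#' @export
setGeneric("toAbsorbance", function(x) standardGeneric("toAbsorbance"))

#' Average replicate scans
#'
#' Arithmetic mean per wavelength within each group, in the current signal
#' domain. The pipeline convention is to average in reflectance and convert
#' to absorbance afterwards.
#'
#' @param x a \linkS4class{SpectraSet}
#' @param by \code{"ear_instrument"} (one averaged spectrum per ear per
#'   instrument) or \code{"ear"} (pool all instruments).
#' @return a \linkS4class{SpectraSet} with replicate key "averaged"
#' @export
setGeneric("averageReplicates",
  function(x, by = c("ear_instrument", "ear")) {
    standardGeneric("averageReplicates")
  })
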