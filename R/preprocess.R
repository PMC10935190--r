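#' Construct a PreprocessSpec
#' @param method one of none, autoscale, mean_center, msc, sg_derivative
#' @param derivative_order,window,poly_order Savitzky-Golay parameters
#'   (sg_derivative only)
#' @return a \linkS4class{PreprocessSpec}
#' @examples
#' preprocessSpec("sg_derivative", 2, 11, 2)  # the D-2,2,11 pretreatment
#' @export
preprocessSpec <- function(method = c("none", "autoscale", "mean_center",
                                      "msc", "sg_derivative"),
                           derivative_order = 2L, window = 11L,
                           poly_order = 2L) {
  method <- match.arg(method)
  methods::new("PreprocessSpec", method = method,
               derivative_order = as.integer(derivative_order),
               window = as.integer(window),
               poly_order = as.integer(poly_order))
}

#' Parse the "D-d,p,w" derivative shorthand
#'
#' "D-2,2,11" means Savitzky-Golay derivative order 2, polynomial order 2,
#' window 11 variables. Plain method names ("none", "msc", ...) are also
#' accepted.
#' @param text shorthand string
#' @return a \linkS4class{PreprocessSpec}
#' @export
parsePretreatment <- function(text) {
  text <- trimws(text)
  if (grepl("^D-", text)) {
    parts <- suppressWarnings(
      as.integer(strsplit(sub("^D-", "", text), ",")[[1]]))
    if (length(parts) != 3L || anyNA(parts))
      stop("cannot parse derivative shorthand: ", text)
    return(preprocessSpec("sg_derivative", derivative_order = parts[1],
                          poly_order = parts[2], window = parts[3]))
  }
  preprocessSpec(text)
}

#' Format a PreprocessSpec as shorthand
#' @param spec a \linkS4class{PreprocessSpec}
#' @export
formatPretreatment <- function(spec) {
  if (spec@method == "sg_derivative")
    sprintf("D-%d,%d,%d", spec@derivative_order, spec@poly_order,
            spec@window)
  else spec@method
}

setMethod("show", "PreprocessSpec", function(object) {
  cat("PreprocessSpec:", formatPretreatment(object), "\n")
})

#' Autoscale a spectra matrix
#'
#' Centers each column to mean 0 and scales to sample SD 1 (n - 1 divisor),
#' returning the statistics so the identical transform can be applied to
#' new rows.
#' @param X matrix, >= 2 rows; columns named by wavelength
#' @return list(X =, center =, scale =)
#' @export
autoscale <- function(X) {
  if (nrow(X) < 2L) stop("autoscale needs at least 2 rows")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0)) {
    bad <- colnames(X)[scl == 0]
    if (is.null(bad)) bad <- which(scl == 0)
    stop("zero-variance column(s), cannot autoscale: ",
         paste(bad, collapse = ", "))
  }
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Multiplicative scatter correction
#'
#' Regresses each row on the reference spectrum by ordinary least squares
#' and returns (row - intercept) / slope. The reference defaults to the
#' column-mean spectrum of X; when correcting validation rows, pass the
#' reference frozen at calibration time.
#' @param X matrix of spectra (rows)
#' @param reference reference spectrum, length = ncol(X)
#' @return list(X =, reference =)
#' @export
msc <- function(X, reference = NULL) {
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != ncol(X))
    stop("reference length must equal ncol(X)")
  if (var(reference) == 0) stop("zero-variance MSC reference")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  out <- X
  for (i in seq_len(nrow(X))) {
    s <- X[i, ]
    b <- sum((s - mean(s)) * rc) / denom
    a <- mean(s) - b * mean(reference)
    out[i, ] <- (s - a) / b
  }
  list(X = out, reference = reference)
}

#' Savitzky-Golay derivative of each spectrum
#'
#' Local polynomial convolution in variable-index space (the non-uniform nm
#' spacing of the grid is deliberately ignored; windows are counted in
#' variables). Edge points are filled with the end-point filters of the
#' same fitted polynomial frame, so the output length equals the input
#' length.
#' @param X matrix of spectra (rows)
#' @param window odd filter length, <= ncol(X)
#' @param poly_order polynomial order (2 or 3)
#' @param derivative_order 0 (smoothing), 1 or 2
#' @return matrix of derivatives, same shape as X
#' @export
sgDerivative <- function(X, window = 11L, poly_order = 2L,
                         derivative_order = 2L) {
  spec <- preprocessSpec("sg_derivative", derivative_order, window,
                         poly_order)  # validates the parameter combination
  if (window > ncol(X))
    stop("window (", window, ") exceeds spectrum length (", ncol(X), ")")
  X %*% t(sg_matrix(ncol(X), window, poly_order, derivative_order))
}

# The SG filter as one len x len linear map: interior points use the
# central filter row, the first/last (window-1)/2 points the end-point
# filter rows of the same fitted polynomial frame (sgolayfilt's layout).
sg_matrix <- function(len, window, poly_order, derivative_order) {
  Fm <- signal::sgolay(p = poly_order, n = window, m = derivative_order)
  Fm <- unclass(Fm)
  k <- (window - 1L) %/% 2L
  M <- matrix(0, len, len)
  for (i in seq_len(k)) {
    M[i, seq_len(window)] <- Fm[i, ]
    M[len - i + 1L, (len - window + 1L):len] <- Fm[window - i + 1L, ]
  }
  central <- Fm[k + 1L, ]
  for (i in (k + 1L):(len - k))
    M[i, (i - k):(i + k)] <- central
  M
}

#' Fit a pretreatment on calibration rows
#'
#' Learns whatever statistics the pretreatment needs (column means/SDs for
#' autoscaling and mean-centering, the mean calibration spectrum for MSC)
#' so that \code{\link{applyPretreatment}} transforms new rows without
#' peeking at them. Savitzky-Golay derivatives are stateless.
#' @param X calibration matrix (rows = scans/ears)
#' @param spec a \linkS4class{PreprocessSpec}
#' @return a fitted-pretreatment list with elements spec and state
#' @export
fitPretreatment <- function(X, spec) {
  state <- switch(spec@method,
    none = list(),
    autoscale = {
      a <- autoscale(X); list(center = a$center, scale = a$scale)
    },
    mean_center = list(center = colMeans(X)),
    msc = list(reference = colMeans(X)),
    sg_derivative = list()
  )
  structure(list(spec = spec, state = state), class = "FittedPretreatment")
}

#' Apply a fitted pretreatment to rows
#' @param fit from \code{\link{fitPretreatment}}
#' @param X matrix of rows to transform
#' @export
applyPretreatment <- function(fit, X) {
  spec <- fit$spec
  switch(spec@method,
    none = X,
    autoscale = sweep(sweep(X, 2, fit$state$center), 2, fit$state$scale,
                      "/"),
    mean_center = sweep(X, 2, fit$state$center),
    msc = msc(X, reference = fit$state$reference)$X,
    sg_derivative = sgDerivative(X, spec@window, spec@poly_order,
                                 spec@derivative_order)
  )
}

#' The default pretreatment survey grid
#'
#' none, autoscale, MSC, and the Savitzky-Golay derivative family over
#' derivative order 1-2, odd windows 9-27 and polynomial order 2-3:
#' 43 candidates in total.
#' @return list of \linkS4class{PreprocessSpec}s
#' @export
defaultPretreatmentSurvey <- function() {
  cands <- list(preprocessSpec("none"), preprocessSpec("autoscale"),
                preprocessSpec("msc"))
  for (d in 1:2)
    for (w in seq(9L, 27L, by = 2L))
      for (p in 2:3)
        cands <- c(cands, list(preprocessSpec("sg_derivative", d, w, p)))
  cands
}

#' Survey pretreatments by cross-validated PLS performance
#'
#' For each candidate pretreatment, fits a PLS calibration with automatic
#' latent-variable selection and reports the number of latent variables,
#' RMSEC, RMSECV, cross-validated R^2 and the SECV/SEC ratio. Candidates
#' are ranked by RMSECV ascending, ties broken by fewer latent variables,
#' then by smaller SECV/SEC ratio. Individual candidate failures are
#' recorded (error column) without aborting the survey.
#'
#' @param X calibration matrix (absorbance, rows = averaged ear scans)
#' @param y response (moisture, \%w.b.)
#' @param candidates list of \linkS4class{PreprocessSpec}s
#' @param cv a \linkS4class{CVScheme}
#' @param maxLV maximum latent variables to fit
#' @return data.frame ordered best-first, one row per candidate
#' @export
optimizePreprocessing <- function(X, y,
                                  candidates = defaultPretreatmentSurvey(),
                                  cv = cvScheme(), maxLV = 20L) {
  if (length(candidates) == 0L) stop("no candidate pretreatments")
  rows <- lapply(candidates, function(spec) {
    res <- tryCatch({
      m <- fitCalibration(X, y, spec = spec, cv = cv, maxLV = maxLV)
      k <- m@nLV
      sec <- sec_from_rmse(m@rmsec[k], nrow(X))
      secv <- sec_from_rmse(m@rmsecv[k], nrow(X))
      data.frame(pretreatment = formatPretreatment(spec), nLV = k,
                 rmsec = m@rmsec[k], rmsecv = m@rmsecv[k],
                 r2cv = m@r2cv[k], secv_sec_ratio = secv / sec,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(pretreatment = formatPretreatment(spec), nLV = NA_integer_,
                 rmsec = NA_real_, rmsecv = NA_real_, r2cv = NA_real_,
                 secv_sec_ratio = NA_real_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  tab <- do.call(rbind, rows)
  ord <- order(is.na(tab$rmsecv), tab$rmsecv, tab$nLV, tab$secv_sec_ratio)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# crude upper bound used only for ranking ties: treat RMSE as if bias-free
sec_from_rmse <- function(rmse, n) rmse * sqrt(n / (n - 1))
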