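#' Construct a Venetian-blinds CV scheme
#' @param n_splits number of blinds (default 10)
#' @param thickness rows per slat (default 1)
#' @return a \linkS4class{CVScheme}
#' @export
cvScheme <- function(n_splits = 10L, thickness = 1L) {
  methods::new("CVScheme", method = "venetian_blinds",
               n_splits = as.integer(n_splits),
               thickness = as.integer(thickness))
}

#' Venetian-blinds split assignment
#'
#' Row i (1-based) goes to split ((i - 1) \%/\% thickness) \%\% n_splits + 1.
#' Rows are taken in file order; no sorting is applied, so reordering the
#' data changes split composition.
#' @param n_rows number of rows
#' @param n_splits number of splits, <= n_rows
#' @param thickness consecutive rows per slat
#' @return list of disjoint 1-based index vectors whose union is all rows
#' @examples
#' venetianBlindsSplits(20, 10)[[1]]  # rows 1 and 11
#' @export
venetianBlindsSplits <- function(n_rows, n_splits, thickness = 1L) {
  if (n_rows < n_splits)
    stop("n_rows (", n_rows, ") must be >= n_splits (", n_splits, ")")
  assign <- ((seq_len(n_rows) - 1L) %/% thickness) %% n_splits + 1L
  lapply(seq_len(n_splits), function(k) which(assign == k))
}

# Single-response NIPALS PLS on a centered problem. Deterministic: for one
# response the weight direction is X'y, no iteration is needed.
nipals_pls <- function(X, y, maxLV) {
  n <- nrow(X); p <- ncol(X)
  maxLV <- min(maxLV, n - 1L, p)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  W <- matrix(0, p, maxLV); P <- matrix(0, p, maxLV)
  Q <- numeric(maxLV); Tm <- matrix(0, n, maxLV)
  ss0 <- sum(Xc^2)
  a <- 0L
  while (a < maxLV) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(ss0))) break
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12 * max(1, ss0)) break
    pvec <- drop(crossprod(Xc, t)) / tt
    q <- sum(yc * t) / tt
    a <- a + 1L
    W[, a] <- w; P[, a] <- pvec; Q[a] <- q; Tm[, a] <- t
    Xc <- Xc - tcrossprod(t, pvec)
    yc <- yc - t * q
  }
  if (a < maxLV) {
    warning("rank deficiency: truncating to ", a, " latent variables")
    W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
    Q <- Q[seq_len(a)]; Tm <- Tm[, seq_len(a), drop = FALSE]
  }
  # regression vectors for every LV count
  B <- matrix(0, p, a)
  if (a > 0L) {
    R <- W %*% solve(crossprod(P, W))   # a x a triangular system
    for (k in seq_len(a))
      B[, k] <- R[, seq_len(k), drop = FALSE] %*% Q[seq_len(k)]
  }
  list(xMean = xm, yMean = ym, W = W, P = P, Q = Q, scores = Tm,
       B = B, maxLV = a)
}

#' Fit a single-response PLS regression
#'
#' NIPALS with single-response deflation: deterministic, orthogonal scores,
#' regression vectors stored for every latent-variable count from 1 to
#' \code{maxLV}. If the predictor matrix runs out of rank before
#' \code{maxLV} components, the model is truncated with a warning.
#'
#' @param X predictor matrix (rows = samples), no missing values
#' @param y response vector
#' @param maxLV maximum number of latent variables
#' @return list with centering vectors, W/P/Q, scores and the matrix B of
#'   regression vectors (column k = k-LV model)
#' @export
fitPLS <- function(X, y, maxLV = 20L) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  nipals_pls(X, y, as.integer(maxLV))
}

pls_predict_raw <- function(core, X, nLV) {
  X <- as.matrix(X)
  if (nLV == 0L) return(rep(core$yMean, nrow(X)))  # intercept-only model
  nLV <- min(nLV, core$maxLV)
  drop(sweep(X, 2, core$xMean) %*% core$B[, nLV]) + core$yMean
}

#' Venetian-blinds cross-validation of the pretreatment + PLS pipeline
#'
#' For every split, the pretreatment statistics and the PLS model are refit
#' on the retained rows only; held-out rows are transformed with the
#' frozen statistics and predicted. Held-out predictions are pooled across
#' splits and summarized per latent-variable count.
#'
#' @param X absorbance matrix (rows = averaged ear scans)
#' @param y response vector
#' @param spec a \linkS4class{PreprocessSpec}
#' @param cv a \linkS4class{CVScheme}
#' @param maxLV maximum latent variables
#' @return list(table = data.frame(lv, rmsecv, r2cv), pred = pooled
#'   held-out prediction matrix, one column per LV)
#' @export
crossValidate <- function(X, y, spec = preprocessSpec("none"),
                          cv = cvScheme(), maxLV = 20L) {
  X <- as.matrix(X)
  splits <- venetianBlindsSplits(nrow(X), cv@n_splits, cv@thickness)
  pred <- matrix(NA_real_, nrow(X), maxLV)
  fitted_lv <- maxLV
  for (held in splits) {
    tr <- setdiff(seq_len(nrow(X)), held)
    if (var(y[tr]) == 0)
      stop("a cross-validation training split has zero-variance response")
    pt <- fitPretreatment(X[tr, , drop = FALSE], spec)
    Xtr <- applyPretreatment(pt, X[tr, , drop = FALSE])
    Xte <- applyPretreatment(pt, X[held, , drop = FALSE])
    core <- suppressWarnings(fitPLS(Xtr, y[tr], maxLV))
    fitted_lv <- min(fitted_lv, core$maxLV)
    for (k in seq_len(core$maxLV))
      pred[held, k] <- pls_predict_raw(core, Xte, k)
  }
  pred <- pred[, seq_len(fitted_lv), drop = FALSE]
  tab <- data.frame(
    lv = seq_len(fitted_lv),
    rmsecv = apply(pred, 2, rmse, ref = y),
    r2cv = apply(pred, 2, function(p) cor(p, y)^2)
  )
  list(table = tab, pred = pred)
}

#' Select the number of latent variables
#'
#' The chosen count is the first local minimum of RMSECV whose divergence
#' from calibration (RMSECV / RMSEC) does not exceed
#' \code{divergence_ratio_max}. Position 1 qualifies as a local minimum if
#' RMSECV[1] <= RMSECV[2]; the last position never does. If no interior
#' local minimum qualifies, the global minimum satisfying the divergence
#' guard is used; if none does, the count minimizing the ratio is returned
#' with a warning.
#'
#' @param rmsec per-LV calibration RMSE
#' @param rmsecv per-LV cross-validation RMSE (same length)
#' @param divergence_ratio_max largest tolerated RMSECV/RMSEC ratio
#' @return chosen number of latent variables (1-based)
#' @examples
#' selectNumLV(c(4, 3, 2, 1.5, 1), c(5, 4, 3, 3.5, 2))  # 3
#' @export
selectNumLV <- function(rmsec, rmsecv, divergence_ratio_max = 1.25) {
  L <- length(rmsecv)
  if (L == 0L || length(rmsec) != L) stop("empty or mismatched sequences")
  if (L == 1L) return(1L)
  ratio <- rmsecv / rmsec
  is_local_min <- vapply(seq_len(L), function(k) {
    if (k == L) return(FALSE)
    left_ok <- k == 1L || rmsecv[k] <= rmsecv[k - 1L]
    left_ok && rmsecv[k] <= rmsecv[k + 1L]
  }, logical(1))
  ok <- ratio <= divergence_ratio_max
  cand <- which(is_local_min & ok)
  if (length(cand)) return(cand[1L])
  glob <- which(ok)
  if (length(glob)) return(glob[which.min(rmsecv[glob])])
  warning("no latent-variable count satisfies the divergence guard; ",
          "returning the count with the smallest RMSECV/RMSEC ratio")
  which.min(ratio)
}

#' Fit a full PLS calibration (pretreatment + PLS + CV + LV selection)
#'
#' The standard calibration path: freeze the pretreatment on the
#' calibration rows, mean-center inside PLS (always, independent of the
#' pretreatment), cross-validate with pretreatment refit inside every
#' split, and choose the latent-variable count by the first-local-minimum
#' rule.
#'
#' @param X absorbance matrix (rows = averaged ear spectra) or a
#'   \linkS4class{SpectraSet} in the absorbance domain
#' @param y response (moisture, \%w.b.)
#' @param spec a \linkS4class{PreprocessSpec}
#' @param cv a \linkS4class{CVScheme}
#' @param maxLV maximum latent variables (default 20)
#' @param nLV fixed latent-variable count (skips automatic selection)
#' @param divergence_ratio_max see \code{\link{selectNumLV}}
#' @param trainingInfo optional provenance list stored in the model
#' @return a \linkS4class{PLSModel}
#' @export
fitCalibration <- function(X, y, spec = preprocessSpec("none"),
                           cv = cvScheme(), maxLV = 20L, nLV = NULL,
                           divergence_ratio_max = 1.25,
                           trainingInfo = list()) {
  grid <- numeric(0)
  if (methods::is(X, "SpectraSet")) {
    if (signalDomain(X) != "absorbance")
      stop("fitCalibration expects absorbance spectra; use toAbsorbance()")
    grid <- wavelengths(X)
    X <- spectraMatrix(X)
  } else {
    X <- as.matrix(X)
    grid <- if (!is.null(colnames(X)))
      suppressWarnings(as.numeric(colnames(X))) else seq_len(ncol(X))
    if (anyNA(grid)) grid <- seq_len(ncol(X))
  }
  pt <- fitPretreatment(X, spec)
  Xp <- applyPretreatment(pt, X)
  core <- fitPLS(Xp, y, maxLV)
  rmsec <- vapply(seq_len(core$maxLV), function(k) {
    rmse(pls_predict_raw(core, Xp, k), y)
  }, numeric(1))
  cvres <- crossValidate(X, y, spec, cv, maxLV)
  L <- min(core$maxLV, nrow(cvres$table))
  rmsecv <- cvres$table$rmsecv[seq_len(L)]
  r2cv <- cvres$table$r2cv[seq_len(L)]
  chosen <- if (is.null(nLV)) {
    selectNumLV(rmsec[seq_len(L)], rmsecv, divergence_ratio_max)
  } else {
    as.integer(min(nLV, L))
  }
  methods::new("PLSModel",
    pretreatment = list(spec = pt$spec, state = pt$state),
    xMean = core$xMean, yMean = core$yMean,
    weights = core$W, loadings = core$P, yloadings = core$Q,
    coefficients = core$B[, seq_len(L), drop = FALSE],
    nLV = chosen, maxLV = as.integer(L), grid = grid,
    rmsec = rmsec[seq_len(L)], rmsecv = rmsecv, r2cv = r2cv,
    cvPredictions = cvres$pred[, seq_len(L), drop = FALSE],
    trainingInfo = c(trainingInfo, list(n = nrow(X))))
}

#' Predict moisture from spectra with a fitted calibration
#'
#' @param object a \linkS4class{PLSModel}
#' @param newdata absorbance matrix (rows = spectra) or an
#'   absorbance-domain \linkS4class{SpectraSet}; the wavelength grid must
#'   match the model fingerprint exactly (no resampling is attempted)
#' @param nLV latent-variable count (default: the model's chosen count)
#' @return numeric vector of predictions
#' @export
setMethod("predict", "PLSModel", function(object, newdata,
                                          nLV = object@nLV) {
  if (methods::is(newdata, "SpectraSet")) {
    if (signalDomain(newdata) != "absorbance")
      stop("predict expects absorbance spectra; use toAbsorbance()")
    if (length(wavelengths(newdata)) != length(object@grid) ||
        any(abs(wavelengths(newdata) - object@grid) > 1e-6))
      stop("wavelength grid does not match the model fingerprint")
    newdata <- spectraMatrix(newdata)
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != length(object@grid))
      stop("wavelength grid does not match the model fingerprint")
  }
  pt <- structure(list(spec = object@pretreatment$spec,
                       state = object@pretreatment$state),
                  class = "FittedPretreatment")
  Xp <- applyPretreatment(pt, newdata)
  core <- list(xMean = object@xMean, yMean = object@yMean,
               B = object@coefficients, maxLV = object@maxLV)
  pls_predict_raw(core, Xp, nLV)
})

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel:", length(object@grid), "wavelengths, pretreatment",
      formatPretreatment(object@pretreatment$spec),
      "\n  nLV =", object@nLV, "of", object@maxLV,
      sprintf("(RMSEC %.3g, RMSECV %.3g)\n",
              object@rmsec[object@nLV], object@rmsecv[object@nLV]))
})

#' Serialize a PLSModel to JSON
#'
#' Full-precision regression vector, grid, pretreatment step (with frozen
#' statistics), centering vectors, chosen latent-variable count and
#' training provenance.
#' @param model a \linkS4class{PLSModel}
#' @param path optional file; when NULL the JSON string is returned
#' @export
modelToJSON <- function(model, path = NULL) {
  spec <- model@pretreatment$spec
  obj <- list(
    grid = model@grid,
    pretreatment = list(
      method = spec@method,
      derivative_order = spec@derivative_order,
      window = spec@window, poly_order = spec@poly_order,
      state = model@pretreatment$state),
    x_mean = model@xMean, y_mean = model@yMean,
    regression_vector = model@coefficients[, model@nLV],
    coefficients = model@coefficients,
    n_lv = model@nLV, max_lv = model@maxLV,
    rmsec = model@rmsec, rmsecv = model@rmsecv, r2cv = model@r2cv,
    training = model@trainingInfo)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Deserialize a PLSModel from JSON
#' @param path file written by \code{\link{modelToJSON}} (or its string)
#' @export
modelFromJSON <- function(path) {
  obj <- jsonlite::fromJSON(path)
  spec <- preprocessSpec(obj$pretreatment$method,
                         derivative_order = obj$pretreatment$derivative_order,
                         window = obj$pretreatment$window,
                         poly_order = obj$pretreatment$poly_order)
  state <- lapply(obj$pretreatment$state, as.numeric)
  B <- as.matrix(obj$coefficients)
  methods::new("PLSModel",
    cvPredictions = matrix(NA_real_, 0L, 0L),
    pretreatment = list(spec = spec, state = state),
    xMean = as.numeric(obj$x_mean), yMean = as.numeric(obj$y_mean),
    weights = matrix(0, nrow(B), 0L), loadings = matrix(0, nrow(B), 0L),
    yloadings = numeric(0),
    coefficients = B, nLV = as.integer(obj$n_lv),
    maxLV = as.integer(obj$max_lv), grid = as.numeric(obj$grid),
    rmsec = as.numeric(obj$rmsec), rmsecv = as.numeric(obj$rmsecv),
    r2cv = as.numeric(obj$r2cv),
    trainingInfo = as.list(obj$training))
}
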