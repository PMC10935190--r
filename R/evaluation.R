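#' Root mean square error (divisor N)
#' @param pred,ref equal-length numeric vectors
#' @export
rmse <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  if (length(pred) == 0L) stop("rmse of an empty vector")
  sqrt(mean((pred - ref)^2))
}

#' Bias and bias-corrected residual SD
#'
#' bias = mean(pred - ref); sep = sqrt(sum((e - bias)^2) / (n - 1)), the
#' "RMSE corrected for bias". Applied to calibration, cross-validation or
#' prediction residuals this gives SEC, SECV or SEP respectively. The exact
#' identity N * RMSE^2 = N * bias^2 + (N - 1) * SEP^2 ties the three
#' statistics together.
#'
#' @param pred,ref equal-length numeric vectors, length >= 2
#' @return list(bias =, sep =)
#' @export
biasSep <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  if (length(pred) < 2L) stop("biasSep needs at least 2 pairs")
  e <- pred - ref
  b <- mean(e)
  list(bias = b, sep = sqrt(sum((e - b)^2) / (length(e) - 1)))
}

#' Recover SEP from printed RMSEP, bias and N
#'
#' Algebraic rearrangement of the identity N RMSE^2 = N bias^2 +
#' (N - 1) SEP^2; used to reconcile reported validation statistics.
#' @param rmsep,bias,n the published triple
#' @export
sepFromRmsepBias <- function(rmsep, bias, n) {
  v <- n * (rmsep^2 - bias^2) / (n - 1)
  if (any(v < 0)) stop("|bias| exceeds RMSEP: inconsistent statistics")
  sqrt(v)
}

#' OLS line of predicted on reference
#' @param pred,ref equal-length numeric vectors
#' @return list(slope =, intercept =)
#' @export
regressionLine <- function(pred, ref) {
  if (length(pred) < 2L) stop("regression needs at least 2 pairs")
  if (var(ref) == 0) stop("reference variance is zero")
  fit <- lm(pred ~ ref)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}

#' Squared Pearson correlation of predicted and reference
#' @param pred,ref equal-length numeric vectors
#' @export
rSquared <- function(pred, ref) {
  if (var(pred) == 0 || var(ref) == 0)
    stop("r-squared undefined for zero-variance input")
  cor(pred, ref)^2
}

#' Ratio of prediction to deviation
#'
#' Two standard forms: \code{rpd(r2 = .)} gives 1 / sqrt(1 - R^2), and
#' \code{rpd(sd = ., sep = .)} gives SD/SEP. The R^2-derived form is the one
#' used for the headline performance classification; both are reported by
#' \code{\link{evaluatePredictions}}.
#'
#' @param r2 coefficient of determination in [0, 1)
#' @param sd reference standard deviation
#' @param sep standard error of prediction (> 0)
#' @export
rpd <- function(r2 = NULL, sd = NULL, sep = NULL) {
  if (!is.null(r2)) {
    if (r2 >= 1) return(Inf)
    if (r2 < 0) stop("r2 must be in [0, 1]")
    return(1 / sqrt(1 - r2))
  }
  if (is.null(sd) || is.null(sep)) stop("supply r2, or sd and sep")
  if (sep <= 0) return(Inf)
  sd / sep
}

#' Performance class of an RPD value
#'
#' Contiguous half-open bands: [0, 2.0) not recommended; [2.0, 2.5) rough
#' screening; [2.5, 3.0) screening; [3.0, 3.5) quality control; [3.5, 4.0)
#' process control; [4.0, Inf) any application. The conventional published
#' band edges leave small gaps (e.g. 1.9-2.0); these are closed upward so
#' every non-negative RPD gets a class and an RPD of 2.9 stays in
#' "screening".
#'
#' @param rpd non-negative RPD value (Inf allowed)
#' @return class label
#' @export
classifyRPD <- function(rpd) {
  if (any(rpd < 0)) stop("RPD must be non-negative")
  labels <- c("not recommended", "rough screening", "screening",
              "quality control", "process control", "any application")
  labels[findInterval(rpd, c(0, 2.0, 2.5, 3.0, 3.5, 4.0))]
}

#' Full calibration/validation statistics for one prediction set
#'
#' Computes RMSE, bias, SEP, the predicted-on-reference OLS line, R^2 (as
#' squared Pearson correlation), both RPD forms and the RPD performance
#' class, and enforces the RMSE/bias/SEP identity.
#'
#' @param pred,ref equal-length numeric vectors, length >= 2
#' @return an \linkS4class{EvaluationReport}
#' @examples
#' r <- evaluatePredictions(c(2, 4, 6), c(1, 3, 7))
#' r@rmse  # 1
#' @export
evaluatePredictions <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch")
  if (length(pred) < 2L) stop("evaluation needs at least 2 pairs")
  n <- length(pred)
  rm <- rmse(pred, ref)
  bs <- biasSep(pred, ref)
  ln <- regressionLine(pred, ref)
  r2 <- rSquared(pred, ref)
  lhs <- n * rm^2
  rhs <- n * bs$bias^2 + (n - 1) * bs$sep^2
  if (abs(lhs - rhs) > 1e-9 * max(1, lhs))
    stop("internal error: RMSE/bias/SEP identity violated")
  rr2 <- rpd(r2 = r2)
  methods::new("EvaluationReport",
    n = as.integer(n), rmse = rm, bias = bs$bias, sep = bs$sep,
    slope = ln$slope, intercept = ln$intercept, r2 = r2,
    rpd_r2 = rr2, rpd_sd = rpd(sd = sd(ref), sep = bs$sep),
    rpd_class = classifyRPD(rr2))
}

#' Round a statistic the way validation tables print it
#'
#' Two significant figures (so 2.887 prints as 2.9, 0.2816 as 0.28,
#' 14.3 as 14), matching the convention of the reported tables. Full
#' precision is always retained in objects and JSON; this only affects
#' rendered tables.
#' @param x numeric
#' @export
roundReported <- function(x) signif(x, 2)

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport: n=%d RMSE=%.3g bias=%.3g SEP=%.3g R2=%.3g\n",
    object@n, object@rmse, object@bias, object@sep, object@r2))
  cat(sprintf("  slope=%.3g intercept=%.3g RPD(R2)=%.3g [%s] RPD(SD)=%.3g\n",
              object@slope, object@intercept, object@rpd_r2,
              object@rpd_class, object@rpd_sd))
})

#' EvaluationReport as a one-row data.frame
#' @param x an \linkS4class{EvaluationReport}
#' @param row.names,optional,... ignored (S3 signature)
#' @export
as.data.frame.EvaluationReport <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(n = x@n, rmse = x@rmse, bias = x@bias, sep = x@sep,
             slope = x@slope, intercept = x@intercept, r2 = x@r2,
             rpd_r2 = x@rpd_r2, rpd_sd = x@rpd_sd,
             rpd_class = x@rpd_class, stringsAsFactors = FALSE)
}

#' Serialize an EvaluationReport to JSON
#' @param report an \linkS4class{EvaluationReport}
#' @export
reportToJSON <- function(report) {
  jsonlite::toJSON(as.list(as.data.frame(report)), auto_unbox = TRUE,
                   digits = NA)
}
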