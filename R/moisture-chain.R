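#' The quadratic ear/whole-plant moisture relationship
#'
#' Ear moisture (EM, \%w.b.) as a quadratic function of whole-plant moisture
#' (WP, \%w.b.): EM = a2 WP^2 + a1 WP + a0 with a2 = 0.028, a1 = -2.24,
#' a0 = 78.3. The curve opens upward with its vertex at WP = -a1/(2 a2) =
#' 40.0, EM = 33.5; field whole-plant moistures (roughly 55-81 \%w.b.) lie
#' on the increasing branch, which is the branch used for inversion.
#'
#' @param a2,a1,a0 quadratic coefficients; defaults are the established
#'   field-calibrated constants and are not refit by this package.
#' @return list with coefficients and the vertex (wp_vertex, em_min)
#' @examples
#' m <- earWholeplantModel()
#' m$wp_vertex  # 40
#' @export
earWholeplantModel <- function(a2 = 0.028, a1 = -2.24, a0 = 78.3) {
  if (a2 <= 0) stop("a2 must be > 0 (upward-opening quadratic)")
  wp_vertex <- -a1 / (2 * a2)
  list(a2 = a2, a1 = a1, a0 = a0,
       wp_vertex = wp_vertex,
       em_min = a2 * wp_vertex^2 + a1 * wp_vertex + a0)
}

#' Ear moisture from whole-plant moisture
#'
#' Direct evaluation of the quadratic curve. Vectorized.
#'
#' @param wp whole-plant moisture, \%w.b., in [0, 100]
#' @param model from \code{\link{earWholeplantModel}}
#' @return ear moisture, \%w.b.
#' @examples
#' earFromWholeplant(70)  # 58.7
#' @export
earFromWholeplant <- function(wp, model = earWholeplantModel()) {
  if (any(wp < 0 | wp > 100))
    stop("whole-plant moisture must be in [0, 100] %w.b.")
  model$a2 * wp^2 + model$a1 * wp + model$a0
}

#' Whole-plant moisture from ear moisture (increasing-branch inverse)
#'
#' Inverts the quadratic on its increasing branch (WP >= vertex), i.e. the
#' larger root (-a1 + sqrt(a1^2 - 4 a2 (a0 - em))) / (2 a2). Ear moistures
#' below the curve minimum (33.5 \%w.b. for the default coefficients) have
#' no real solution; by default this is an error rather than a silent clamp,
#' because the relationship is not characterized in that regime.
#'
#' @param em ear moisture, \%w.b.
#' @param model from \code{\link{earWholeplantModel}}
#' @param strict if FALSE, return NA (with no error) where em is below the
#'   curve minimum; used by the pipeline to record per-ear failures.
#' @return whole-plant moisture, \%w.b.
#' @examples
#' wholeplantFromEar(58.7)  # 70
#' @export
wholeplantFromEar <- function(em, model = earWholeplantModel(),
                              strict = TRUE) {
  disc <- model$a1^2 - 4 * model$a2 * (model$a0 - em)
  disc[abs(disc) < 1e-9] <- 0   # snap the discriminant-zero (vertex) case
  bad <- disc < 0
  if (any(bad) && strict)
    stop("ear moisture below the quadratic minimum (",
         format(model$em_min), " %w.b.); no real whole-plant solution for: ",
         paste(format(em[bad]), collapse = ", "))
  disc <- pmax(disc, 0)
  wp <- (-model$a1 + sqrt(disc)) / (2 * model$a2)
  wp[bad] <- NA_real_
  wp
}

method_result <- function(method, predictions, report) {
  methods::new("MethodResult", method = method,
               predictions = predictions, report = report)
}

#' Method 1: whole-plant moisture from oven-dried ear moisture
#'
#' Inverts the quadratic ear/whole-plant curve at the oven reference ear
#' moisture of each plant and evaluates the predictions against reference
#' whole-plant moisture.
#'
#' @param em_oven oven-dried ear moisture, \%w.b.
#' @param wp_ref reference whole-plant moisture, \%w.b.
#' @param ear_id optional ids (defaults to 1..n)
#' @return a \linkS4class{MethodResult}
#' @export
runMethod1 <- function(em_oven, wp_ref, ear_id = NULL) {
  stopifnot(length(em_oven) == length(wp_ref))
  if (is.null(ear_id)) ear_id <- as.character(seq_along(em_oven))
  wp_pred <- wholeplantFromEar(em_oven, strict = FALSE)
  status <- ifelse(is.na(wp_pred), "em_below_curve_minimum", "ok")
  ok <- status == "ok"
  pred <- data.frame(ear_id = ear_id, predicted_ear_moisture = em_oven,
                     predicted_wholeplant_moisture = wp_pred,
                     status = status, stringsAsFactors = FALSE)
  method_result("method1_oven_chain", pred,
                evaluatePredictions(wp_pred[ok], wp_ref[ok]))
}

chain_predict <- function(model, spectra, reference, direct) {
  if (signalDomain(spectra) == "reflectance") {
    spectra <- toAbsorbance(averageReplicates(spectra, by = "ear"))
  }
  if (ncol(spectra) == 0L) stop("empty spectra set")
  info <- scanInfo(spectra)
  yhat <- predict(model, spectra)
  idx <- match(info$ear_id, reference$ear_id)
  if (anyNA(idx))
    stop("spectra contain ear ids absent from the reference table")
  if (direct) {
    em_pred <- rep(NA_real_, length(yhat))
    wp_pred <- yhat
    status <- rep("ok", length(yhat))
  } else {
    em_pred <- yhat
    wp_pred <- wholeplantFromEar(em_pred, strict = FALSE)
    status <- ifelse(is.na(wp_pred), "em_below_curve_minimum", "ok")
  }
  list(pred = data.frame(ear_id = info$ear_id,
                         predicted_ear_moisture = em_pred,
                         predicted_wholeplant_moisture = wp_pred,
                         status = status, stringsAsFactors = FALSE),
       wp_ref = reference$wholeplant_moisture_wb[idx])
}

#' Method 2: NIRS-predicted ear moisture chained through the quadratic curve
#'
#' Predicts ear moisture from ear spectra with a fitted PLS calibration,
#' inverts the ear/whole-plant curve, and evaluates against reference
#' whole-plant moisture. Raw reflectance scans are replicate-averaged per
#' ear (pooling instruments) and converted to absorbance first; an
#' absorbance SpectraSet is used as-is.
#'
#' @param model a \linkS4class{PLSModel} trained on ear moisture
#' @param spectra a \linkS4class{SpectraSet} of the validation scans
#' @param reference data.frame with ear_id and wholeplant_moisture_wb
#' @return a \linkS4class{MethodResult}
#' @export
runMethod2 <- function(model, spectra, reference) {
  p <- chain_predict(model, spectra, reference, direct = FALSE)
  ok <- p$pred$status == "ok"
  method_result("method2_nirs_chain", p$pred,
                evaluatePredictions(
                  p$pred$predicted_wholeplant_moisture[ok], p$wp_ref[ok]))
}

#' Method 3: direct NIRS prediction of whole-plant moisture from ear scans
#'
#' @param model a \linkS4class{PLSModel} trained on whole-plant moisture
#' @param spectra a \linkS4class{SpectraSet} of the validation scans
#' @param reference data.frame with ear_id and wholeplant_moisture_wb
#' @return a \linkS4class{MethodResult}
#' @export
runMethod3 <- function(model, spectra, reference) {
  p <- chain_predict(model, spectra, reference, direct = TRUE)
  method_result("method3_direct", p$pred,
                evaluatePredictions(
                  p$pred$predicted_wholeplant_moisture, p$wp_ref))
}

setMethod("show", "MethodResult", function(object) {
  cat("MethodResult <", object@method, ">:",
      nrow(object@predictions), "ears (",
      sum(object@predictions$status != "ok"), "failed )\n")
  show(object@report)
})
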