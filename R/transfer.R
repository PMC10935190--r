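#' Enumerate the calibration-transfer design
#'
#' Calibration subsets are every non-empty subset of the instrument ids
#' (7 subsets for 3 instruments); validation targets are each single
#' instrument plus the pooled "All".
#' @param instruments character vector of instrument ids
#' @return list(subsets = list of id vectors, targets = character)
#' @export
transferDesign <- function(instruments) {
  instruments <- as.character(instruments)
  if (anyDuplicated(instruments)) stop("duplicate instrument ids")
  n <- length(instruments)
  if (n < 1L) stop("at least one instrument is required")
  subsets <- list()
  for (size in seq_len(n))
    subsets <- c(subsets,
                 utils::combn(instruments, size, simplify = FALSE))
  list(subsets = subsets, targets = c(instruments, "All"))
}

subset_label <- function(ids, all_ids) {
  if (length(ids) == length(all_ids)) "All" else paste(ids, collapse = "&")
}

#' Run the instrument-subset calibration/validation matrix
#'
#' For every non-empty subset of instruments, fits a calibration on the
#' season-A scans of those instruments (replicates averaged per ear per
#' instrument, converted to absorbance, latent-variable count re-selected
#' per subset) and validates it on season B, once per single-instrument
#' target and once on all instruments pooled. Cells for which prediction
#' fails are recorded with an error message and the run continues.
#'
#' @param calSpectra,calRef calibration-season scans
#'   (reflectance \linkS4class{SpectraSet}) and reference table
#' @param valSpectra,valRef validation-season scans and reference table
#' @param target response variable: "ear" or "wholeplant" moisture
#' @param spec pretreatment applied in every subset (default the
#'   second-derivative D-2,2,11 filter); set \code{optimize = TRUE} to
#'   re-survey pretreatments per subset instead
#' @param cv a \linkS4class{CVScheme}
#' @param maxLV maximum latent variables
#' @param optimize re-run the pretreatment survey within each subset
#' @return a \linkS4class{TransferReport}
#' @export
runTransfer <- function(calSpectra, calRef, valSpectra, valRef,
                        target = c("ear", "wholeplant"),
                        spec = preprocessSpec("sg_derivative", 2, 11, 2),
                        cv = cvScheme(), maxLV = 20L, optimize = FALSE) {
  target <- match.arg(target)
  ycol <- if (target == "ear") "ear_moisture_wb" else
    "wholeplant_moisture_wb"
  all_ids <- sort(unique(scanInfo(calSpectra)$instrument_id))
  design <- transferDesign(all_ids)
  val_avg <- toAbsorbance(averageReplicates(valSpectra,
                                            by = "ear_instrument"))
  val_info <- scanInfo(val_avg)
  cal_rows <- list(); val_rows <- list(); models <- list()
  for (ids in design$subsets) {
    lab <- subset_label(ids, all_ids)
    fit <- tryCatch({
      sub <- filterInstruments(calSpectra, ids)
      sub <- toAbsorbance(averageReplicates(sub, by = "ear_instrument"))
      y <- calRef[[ycol]][match(scanInfo(sub)$ear_id, calRef$ear_id)]
      use_spec <- spec
      if (optimize) {
        surv <- optimizePreprocessing(spectraMatrix(sub), y, cv = cv,
                                      maxLV = maxLV)
        use_spec <- parsePretreatment(surv$pretreatment[1L])
      }
      fitCalibration(sub, y, spec = use_spec, cv = cv, maxLV = maxLV,
                     trainingInfo = list(instruments = ids,
                                         target = target))
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      cal_rows[[lab]] <- data.frame(
        subset = lab, n = NA_integer_, nLV = NA_integer_,
        SEC = NA_real_, R2C = NA_real_, SECV = NA_real_, R2CV = NA_real_,
        pretreatment = NA_character_, error = conditionMessage(fit),
        stringsAsFactors = FALSE)
      next
    }
    models[[lab]] <- fit
    # calibration statistics at the chosen LV count
    sub <- toAbsorbance(averageReplicates(filterInstruments(calSpectra,
                                                            ids),
                                          by = "ear_instrument"))
    y <- calRef[[ycol]][match(scanInfo(sub)$ear_id, calRef$ear_id)]
    yc_hat <- predict(fit, sub)
    cv_pred <- fit@cvPredictions[, fit@nLV]
    cal_rows[[lab]] <- data.frame(
      subset = lab, n = length(y), nLV = fit@nLV,
      SEC = biasSep(yc_hat, y)$sep, R2C = rSquared(yc_hat, y),
      SECV = biasSep(cv_pred, y)$sep, R2CV = rSquared(cv_pred, y),
      pretreatment = formatPretreatment(fit@pretreatment$spec),
      error = NA_character_, stringsAsFactors = FALSE)
    for (tgt in design$targets) {
      cell <- tryCatch({
        keep <- if (tgt == "All") rep(TRUE, nrow(val_info)) else
          val_info$instrument_id == tgt
        if (!any(keep)) stop("no validation scans for instrument ", tgt)
        vs <- val_avg[, keep]
        yv <- valRef[[ycol]][match(scanInfo(vs)$ear_id, valRef$ear_id)]
        pv <- predict(fit, vs)
        ev <- evaluatePredictions(pv, yv)
        data.frame(subset = lab, valTarget = tgt,
                   cell = paste0(lab, "\u2192", tgt),
                   n = ev@n, R2P = ev@r2, RMSEP = ev@rmse,
                   SEP = ev@sep, Bias = ev@bias,
                   Intercept = ev@intercept, Slope = ev@slope,
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(subset = lab, valTarget = tgt,
                   cell = paste0(lab, "\u2192", tgt),
                   n = NA_integer_, R2P = NA_real_, RMSEP = NA_real_,
                   SEP = NA_real_, Bias = NA_real_, Intercept = NA_real_,
                   Slope = NA_real_, error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      val_rows[[length(val_rows) + 1L]] <- cell
    }
  }
  methods::new("TransferReport",
               calibration = do.call(rbind, unname(cal_rows)),
               validation = do.call(rbind, unname(val_rows)),
               models = models)
}

#' Render a TransferReport as tab-separated tables
#'
#' Calibration table: one column per calibration subset, rows SEC, R2C,
#' SECV, R2CV, nLV. Validation table: one column per subset-to-target cell
#' (e.g. "1->3", "2&3->1"), rows R2P, RMSEP, SEP, Bias, Intercept,
#' Slope. Values are rounded to two significant figures, the convention of
#' the rendered tables; full precision stays in the report object.
#' @param report a \linkS4class{TransferReport}
#' @param cells optional character vector of validation cell labels (such as
#'   "All→All" or "2&3→1") selecting and ordering the validation
#'   columns; default all cells
#' @return list(calibration = character lines, validation = character lines)
#' @export
renderTransferTables <- function(report, cells = NULL) {
  cal <- report@calibration[is.na(report@calibration$error), , drop = FALSE]
  cal_stats <- c("SEC", "R2C", "SECV", "R2CV", "nLV")
  cal_tab <- vapply(cal_stats, function(s) {
    v <- cal[[s]]
    if (s == "nLV") as.character(v) else
      format(roundReported(v), trim = TRUE)
  }, character(nrow(cal)))
  cal_lines <- c(paste(c("Parameter", cal$subset), collapse = "\t"),
                 vapply(seq_along(cal_stats), function(i) {
                   paste(c(cal_stats[i],
                           if (nrow(cal)) cal_tab[, i] else character(0)),
                         collapse = "\t")
                 }, character(1)))
  val <- report@validation[is.na(report@validation$error), , drop = FALSE]
  if (!is.null(cells)) {
    idx <- match(cells, val$cell)
    if (anyNA(idx))
      stop("unknown validation cell(s): ",
           paste(cells[is.na(idx)], collapse = ", "))
    val <- val[idx, , drop = FALSE]
  }
  val_stats <- c("R2P", "RMSEP", "SEP", "Bias", "Intercept", "Slope")
  val_lines <- c(paste(c("Parameter", val$cell), collapse = "\t"),
                 vapply(val_stats, function(s) {
                   paste(c(s, format(roundReported(val[[s]]), trim = TRUE)),
                         collapse = "\t")
                 }, character(1)))
  list(calibration = cal_lines, validation = val_lines)
}

#' Parse a rendered validation table back into a data.frame
#'
#' Inverse of the validation half of \code{\link{renderTransferTables}},
#' to printed precision.
#' @param lines character vector of tab-separated lines
#' @export
parseValidationTable <- function(lines) {
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]][-1L]
  out <- data.frame(cell = header, stringsAsFactors = FALSE)
  for (row in cells[-1L])
    out[[row[1L]]] <- as.numeric(row[-1L])
  out
}

#' Write a TransferReport to a directory
#'
#' Writes calibration_table.tsv, validation_table.tsv and report.json
#' (full precision).
#' @param report a \linkS4class{TransferReport}
#' @param dir output directory (created if needed)
#' @export
writeTransferReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- renderTransferTables(report)
  writeLines(tabs$calibration, file.path(dir, "calibration_table.tsv"))
  writeLines(tabs$validation, file.path(dir, "validation_table.tsv"))
  jsonlite::write_json(
    list(calibration = report@calibration, validation = report@validation),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

setMethod("show", "TransferReport", function(object) {
  cat("TransferReport:", nrow(object@calibration), "calibration subsets,",
      nrow(object@validation), "validation cells\n")
})
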