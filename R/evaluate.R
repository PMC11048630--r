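#' Mean absolute error on the GPR percent scale
#'
#' `MAE = mean(|measured - predicted|)`, the clinical headline metric for
#' GPR prediction (both vectors in percent).
#'
#' @param measured,predicted Equal-length nonempty numeric vectors (percent).
#' @return MAE in GPR percentage points.
#' @export
gpr_mae <- function(measured, predicted) {
  if (length(measured) == 0) stop("empty input")
  if (length(measured) != length(predicted)) {
    stop("measured and predicted must have equal length")
  }
  mean(abs(measured - predicted))
}

#' Classify a GPR against tolerance and action limits
#'
#' TG-218 style triage: `pass` at or above the tolerance limit,
#' `tolerance_zone` between the action and tolerance limits (investigate),
#' `action` below the action limit (do not treat without intervention).
#'
#' @param gpr GPR percent(s) in \[0, 100\] (vectorised).
#' @param criterion `"2_2"`, `"3_2"` or `"3_3"`.
#' @return Character vector in `{"pass", "tolerance_zone", "action"}`.
#' @export
classify_limit <- function(gpr, criterion) {
  crit <- gamma_criteria()
  row <- crit[crit$criterion == criterion, ]
  if (nrow(row) != 1) stop("unknown gamma criterion '", criterion, "'")
  if (any(gpr < 0 | gpr > 100)) stop("GPR outside [0, 100]")
  ifelse(gpr >= row$tolerance_limit, "pass",
         ifelse(gpr >= row$action_limit, "tolerance_zone", "action"))
}

#' Prediction-error band counts
#'
#' Counts samples with absolute prediction error below each band boundary,
#' using strict `<` for the inner bands: with the default bands (3, 5) the
#' report gives `lt3` = #(|e| < 3), `lt5` = #(|e| < 5) and `ge5` =
#' #(|e| >= 5); an error of exactly 5 falls in the flagged `ge5` band, and
#' `lt5 + ge5 = N`.
#'
#' @param measured,predicted Equal-length numeric vectors (percent).
#' @param bands Increasing band boundaries, default `c(3, 5)`.
#' @return Named integer vector: one cumulative `lt<b>` count per band plus
#'   `ge<last>`.
#' @export
error_bands <- function(measured, predicted, bands = c(3, 5)) {
  if (length(measured) != length(predicted)) {
    stop("measured and predicted must have equal length")
  }
  err <- abs(measured - predicted)
  counts <- vapply(bands, function(b) sum(err < b), integer(1))
  names(counts) <- paste0("lt", bands)
  counts[paste0("ge", bands[length(bands)])] <- sum(err >= bands[length(bands)])
  counts
}

#' Flag plans whose prediction deviates beyond a threshold
#'
#' The measurement-anomaly audit: plans where |predicted - measured| exceeds
#' the threshold (default 5 GPR points) are flagged for physicist
#' re-measurement, since large deviations on the training side in particular
#' indicate suspect QA measurements rather than model error.  The report
#' labels each flagged plan's partition explicitly.  A relabel-and-retrain
#' round trip is supported by [apply_relabels()]: replace the flagged labels
#' with re-measured values and refit with [fit_criterion()].
#'
#' @param sample_id Plan identifiers.
#' @param measured,predicted GPR percent vectors.
#' @param threshold Flagging threshold in GPR points (default 5; strict `>`).
#' @param partition Optional per-plan partition labels (`"train"`/`"test"`).
#' @return An `anomaly_report` data frame: `sample_id`, `measured`,
#'   `predicted`, `deviation` (predicted - measured), `partition`; attribute
#'   `threshold`.
#' @export
flag_anomalies <- function(sample_id, measured, predicted, threshold = 5,
                           partition = NULL) {
  dev <- predicted - measured
  keep <- abs(dev) > threshold
  if (is.null(partition)) partition <- rep(NA_character_, length(sample_id))
  out <- data.frame(
    sample_id = sample_id[keep],
    measured = measured[keep],
    predicted = predicted[keep],
    deviation = dev[keep],
    partition = partition[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("anomaly_report", "data.frame")
  out
}

#' Replace measured labels for re-measured plans
#'
#' @param data Labelled plan table.
#' @param relabels Data frame with `sample_id` and the GPR column(s) to
#'   replace (e.g. `gpr_2_2`).
#' @return The corrected plan table.
#' @export
apply_relabels <- function(data, relabels) {
  idx <- match(relabels$sample_id, data$sample_id)
  if (anyNA(idx)) stop("relabels contain unknown sample_id(s)")
  for (col in intersect(names(relabels), gpr_columns())) {
    data[idx, col] <- relabels[[col]]
  }
  data
}

#' Evaluate a fitted model on a labelled plan table
#'
#' @param fit An `mbnn_fit`.
#' @param data Labelled plan table (default: the fit's held-out test rows
#'   must be supplied by the caller).
#' @return A `gpr_eval` list: `mae` (percent), `bands` (error-band counts),
#'   `limits` (cross-tabulation of measured vs predicted limit classes) and
#'   the per-plan prediction table.
#' @export
evaluate_fit <- function(fit, data) {
  col <- criterion_column(fit$criterion)
  if (!col %in% names(data)) stop("table has no measured column '", col, "'")
  pred <- predict(fit, data)
  measured <- data[[col]]
  cls <- factor(classify_limit(pred, fit$criterion),
                levels = c("pass", "tolerance_zone", "action"))
  cls_meas <- factor(classify_limit(measured, fit$criterion),
                     levels = c("pass", "tolerance_zone", "action"))
  structure(list(
    criterion = fit$criterion,
    n = nrow(data),
    mae = gpr_mae(measured, pred),
    bands = error_bands(measured, pred),
    limits = table(measured = cls_meas, predicted = cls),
    predictions = data.frame(sample_id = data$sample_id, measured = measured,
                             predicted = unname(pred),
                             abs_error = abs(measured - unname(pred)),
                             limit_class = as.character(cls),
                             stringsAsFactors = FALSE)
  ), class = "gpr_eval")
}

#' @exportS3Method base::print
print.gpr_eval <- function(x, ...) {
  cat("GPR evaluation (", gsub("_", "%/", x$criterion), " mm), n = ", x$n,
      "\n", sep = "")
  cat("  MAE:", round(x$mae, 3), "GPR points\n")
  cat("  error bands:", paste(names(x$bands), x$bands, sep = "=", collapse = ", "),
      "\n")
  print(x$limits)
  invisible(x)
}
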