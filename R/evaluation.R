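#' Paired true/predicted peak accelerations
#'
#' Container for evaluation: one (measured, predicted) peak pair per test
#' window, in g, each carrying its movement code and category.
#'
#' @param y Measured peak accelerations (g).
#' @param yhat Predicted peak accelerations (g).
#' @param movement_code Character vector of movement codes (recycled if
#'   length 1).
#' @param category Character vector of categories (`NF`/`LF`/`HF`).
#' @return An `ffh_predictions` data frame with columns `y`, `yhat`,
#'   `movement_code`, `category`.
#' @export
prediction_set <- function(y, yhat, movement_code = NA_character_,
                           category = NA_character_) {
  if (length(y) < 1L) stop("prediction set must contain at least one pair")
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  if (!all(is.finite(y)) || !all(is.finite(yhat))) {
    stop("prediction set requires finite values")
  }
  df <- data.frame(y = y, yhat = yhat,
                   movement_code = rep_len(movement_code, length(y)),
                   category = rep_len(category, length(y)),
                   stringsAsFactors = FALSE)
  class(df) <- c("ffh_predictions", "data.frame")
  df
}

#' Mean absolute error of predicted peaks (g)
#'
#' MAE = (1/N) * sum |yhat_i - y_i|.
#'
#' @param predictions An [prediction_set()].
#' @return MAE in g.
#' @export
mae <- function(predictions) {
  stopifnot(inherits(predictions, "ffh_predictions"))
  mean(abs(predictions$yhat - predictions$y))
}

#' Mean squared error of predicted peaks (g^2)
#'
#' MSE = (1/N) * sum (yhat_i - y_i)^2.
#'
#' @param predictions An [prediction_set()].
#' @return MSE in g^2.
#' @export
mse <- function(predictions) {
  stopifnot(inherits(predictions, "ffh_predictions"))
  mean((predictions$yhat - predictions$y)^2)
}

#' Classify a peak acceleration as FFH risk
#'
#' A peak of 9 g or higher indicates a fall-from-height; the boundary value
#' itself counts as FFH.
#'
#' @param peak_g Peak acceleration(s) in g.
#' @param threshold_g Risk threshold (default 9 g).
#' @return Character vector, `"FFH"` or `"non-FFH"` per input.
#' @export
classify_risk <- function(peak_g, threshold_g = 9) {
  if (!all(is.finite(peak_g))) stop("peak_g must be finite")
  ifelse(peak_g >= threshold_g, "FFH", "non-FFH")
}

#' Confusion counts and classification metrics at the risk threshold
#'
#' Both the measured and the predicted peak are thresholded at
#' `threshold_g`; the measured label is the ground truth. Sensitivity is the
#' detected fraction of true FFHs, specificity the correctly cleared
#' fraction of non-FFHs, accuracy the overall agreement, all in percent. A
#' metric whose denominator is zero (no positives, or no negatives) is
#' reported as `NA` and listed in `undefined` instead of being silently
#' zeroed.
#'
#' @param predictions An [prediction_set()].
#' @param threshold_g Risk threshold in g (default 9).
#' @return List with `counts` (`TP`, `FP`, `TN`, `FN`), `sensitivity_pct`,
#'   `specificity_pct`, `accuracy_pct`, `threshold_g` and `undefined`
#'   (character vector of metrics with zero denominators).
#' @export
confusion_metrics <- function(predictions, threshold_g = 9) {
  stopifnot(inherits(predictions, "ffh_predictions"))
  truth <- predictions$y >= threshold_g
  pred <- predictions$yhat >= threshold_g
  tp <- sum(truth & pred)
  fp <- sum(!truth & pred)
  tn <- sum(!truth & !pred)
  fn <- sum(truth & !pred)
  undefined <- character(0)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    undefined <- c(undefined, "sensitivity")
    NA_real_
  }
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else {
    undefined <- c(undefined, "specificity")
    NA_real_
  }
  list(counts = list(TP = tp, FP = fp, TN = tn, FN = fn),
       sensitivity_pct = sens, specificity_pct = spec,
       accuracy_pct = 100 * (tp + tn) / nrow(predictions),
       threshold_g = threshold_g, undefined = undefined)
}

#' Per-movement summary of true and predicted peaks
#'
#' One row per movement code present in the prediction set: pair count,
#' mean and standard deviation (n-1 denominator; `NA` for a single pair) of
#' the measured and predicted peaks.
#'
#' @param predictions An [prediction_set()].
#' @return Data frame with columns `movement_code`, `n`, `true_mean`,
#'   `true_sd`, `pred_mean`, `pred_sd`.
#' @export
per_movement_summary <- function(predictions) {
  stopifnot(inherits(predictions, "ffh_predictions"))
  codes <- sort(unique(predictions$movement_code))
  do.call(rbind, lapply(codes, function(code) {
    sub <- predictions[predictions$movement_code == code, ]
    data.frame(
      movement_code = code, n = nrow(sub),
      true_mean = mean(sub$y),
      true_sd = if (nrow(sub) > 1) stats::sd(sub$y) else NA_real_,
      pred_mean = mean(sub$yhat),
      pred_sd = if (nrow(sub) > 1) stats::sd(sub$yhat) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
}

#' Full evaluation report for one trained model
#'
#' Bundles the regression errors, the thresholded confusion metrics and the
#' per-movement summary. As a sanity invariant the report writer asserts
#' MAE <= sqrt(MSE) (Jensen's inequality), which holds for every prediction
#' set.
#'
#' @param predictions An [prediction_set()].
#' @param threshold_g Risk threshold in g (default 9).
#' @param model_label Optional label (architecture/loss) carried in the
#'   report.
#' @return An `ffh_report`: list with `model_label`, `n`, `mae_g`,
#'   `mse_g2`, `threshold_g`, `confusion`, `per_movement`.
#' @export
evaluation_report <- function(predictions, threshold_g = 9,
                              model_label = "model") {
  m1 <- mae(predictions)
  m2 <- mse(predictions)
  stopifnot(m1 <= sqrt(m2) + 1e-12)     # Jensen: mean|e| <= sqrt(mean e^2)
  structure(
    list(model_label = model_label, n = nrow(predictions),
         mae_g = m1, mse_g2 = m2, threshold_g = threshold_g,
         confusion = confusion_metrics(predictions, threshold_g),
         per_movement = per_movement_summary(predictions)),
    class = "ffh_report"
  )
}

#' @export
print.ffh_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("<ffh_report> %s: n=%d, MAE %.3f g, MSE %.3f g^2\n",
              x$model_label, x$n, x$mae_g, x$mse_g2))
  cat(sprintf("  threshold %.1f g: TP=%d FP=%d TN=%d FN=%d\n",
              x$threshold_g, cm$counts$TP, cm$counts$FP, cm$counts$TN,
              cm$counts$FN))
  cat(sprintf("  accuracy %.1f%%, sensitivity %s, specificity %s\n",
              cm$accuracy_pct,
              ifelse(is.na(cm$sensitivity_pct), "undefined",
                     sprintf("%.1f%%", cm$sensitivity_pct)),
              ifelse(is.na(cm$specificity_pct), "undefined",
                     sprintf("%.1f%%", cm$specificity_pct))))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON and its per-movement table as CSV.
#'
#' @param report An `ffh_report`.
#' @param json_path Output JSON path (`NULL` to skip).
#' @param csv_path Output CSV path for the per-movement table (`NULL` to
#'   skip).
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "ffh_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  if (!is.null(csv_path)) {
    data.table::fwrite(report$per_movement, csv_path)
  }
  invisible(report)
}
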