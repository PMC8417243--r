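# Confusion counts and the seizure-prediction indicator suite. Pre-ictal is
# the positive class. Specificity, sensitivity, PPV, NPV and accuracy are
# reported as percentages; FPR and F1 as ratios. Metrics with a zero
# denominator are undefined and reported as NA, never as 0.

#' Confusion counts
#'
#' @param predictions,truth Equal-length label vectors
#'   (`"pre_ictal"`/`"inter_ictal"`).
#' @param positive_class Positive class label (default `"pre_ictal"`).
#' @return Object of class `confusion_counts`: list with `TP`, `FP`, `TN`,
#'   `FN` and `total`.
#' @export
confusion_counts <- function(predictions, truth,
                             positive_class = "pre_ictal") {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth must have equal length", call. = FALSE)
  }
  p <- predictions == positive_class
  t <- truth == positive_class
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 TN = sum(!p & !t), FN = sum(!p & t),
                 total = length(truth)),
            class = "confusion_counts")
}

.safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Evaluation indicator suite from confusion counts
#'
#' Accuracy = 100 (TP+TN)/total; specificity = 100 TN/(TN+FP); sensitivity
#' = 100 TP/(TP+FN); PPV = 100 TP/(TP+FP); NPV = 100 TN/(TN+FN); FPR =
#' FP/(FP+TN) (ratio); F1 = 2TP/(2TP+FP+FN) (ratio).
#'
#' @param c A [confusion_counts()] object.
#' @return Object of class `metrics_report`: list with `specificity`,
#'   `sensitivity`, `ppv`, `npv`, `fpr`, `accuracy`, `f1`.
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$total <= 0) stop("no evaluated segments", call. = FALSE)
  structure(list(
    specificity = 100 * .safe_ratio(c$TN, c$TN + c$FP),
    sensitivity = 100 * .safe_ratio(c$TP, c$TP + c$FN),
    ppv = 100 * .safe_ratio(c$TP, c$TP + c$FP),
    npv = 100 * .safe_ratio(c$TN, c$TN + c$FN),
    fpr = .safe_ratio(c$FP, c$FP + c$TN),
    accuracy = 100 * .safe_ratio(c$TP + c$TN, c$total),
    f1 = .safe_ratio(2 * c$TP, 2 * c$TP + c$FP + c$FN)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("specificity %.2f%%  sensitivity %.2f%%  PPV %.2f%%  ",
                     "NPV %.2f%%  FPR %.4f  accuracy %.2f%%  F1 %.4f\n"),
              x$specificity, x$sensitivity, x$ppv, x$npv, x$fpr,
              x$accuracy, x$f1))
  invisible(x)
}

#' Per-case report table with unweighted average row
#'
#' @param case_results Named list of [compute_metrics()] results, one per
#'   case.
#' @param path Optional CSV output path (columns
#'   `case_id,specificity,sensitivity,ppv,npv,fpr,accuracy,f1`).
#' @return Data frame, one row per case plus a final `"Average"` row
#'   holding the unweighted mean of each column over cases (undefined
#'   entries excluded).
#' @export
per_case_report <- function(case_results, path = NULL) {
  if (length(case_results) == 0) stop("no case results", call. = FALSE)
  cols <- c("specificity", "sensitivity", "ppv", "npv", "fpr", "accuracy",
            "f1")
  rows <- lapply(case_results, function(m) {
    as.data.frame(m[cols], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- cbind(case_id = names(case_results), df)
  avg <- data.frame(case_id = "Average", t(colMeans(df[, cols],
                                                    na.rm = TRUE)))
  names(avg) <- names(df)
  out <- rbind(df, avg)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
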