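# Confusion counts and the derived classification metrics.

#' Confusion counts and classification metrics
#'
#' Hard labels are taken at `threshold` on the ASD probability (ASD = 1 is
#' the positive class). Accuracy is the proportion of correct predictions;
#' precision = TP / (TP + FP); recall = TP / (TP + FN); F1 is the harmonic
#' mean of precision and recall. A ratio with zero denominator is reported as
#' 0 and flagged in the `flags` field rather than NaN.
#'
#' @param truth 0/1 vector of true labels.
#' @param prob predicted ASD probabilities (or hard 0/1 predictions).
#' @param threshold decision threshold.
#' @return Object of class `"gaze_metrics"`: counts `tp`, `fp`, `fn`, `tn`,
#'   metrics `accuracy`, `precision`, `recall`, `f1`, and `flags` naming any
#'   zero-denominator metrics.
#' @export
classification_metrics <- function(truth, prob, threshold = 0.5) {
  stopifnot(length(truth) == length(prob), length(truth) > 0)
  truth <- as.integer(truth)
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  flags <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) { flags <<- c(flags, what); 0 } else num / den
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- f1_from_pr(precision, recall)
  if (!is.null(attr(f1, "flag"))) flags <- c(flags, "f1")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / length(truth),
                 precision = precision, recall = recall,
                 f1 = as.numeric(f1), flags = flags),
            class = "gaze_metrics")
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * P * R / (P + R)`; equals the common value when
#' `P == R`. When both are zero the score is undefined and reported as 0 with
#' attribute `flag = "undefined"`.
#'
#' @param precision,recall values in `[0, 1]`.
#' @return F1 score (numeric scalar, possibly flagged).
#' @export
f1_from_pr <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0)
    return(structure(0, flag = "undefined"))
  2 * precision * recall / (precision + recall)
}

#' @export
print.gaze_metrics <- function(x, ...) {
  cat(sprintf("<gaze_metrics> n=%d  acc=%.4f  P=%.4f  R=%.4f  F1=%.4f\n",
              x$tp + x$fp + x$fn + x$tn, x$accuracy, x$precision, x$recall, x$f1))
  cat(sprintf("  counts: TP=%d FP=%d FN=%d TN=%d%s\n", x$tp, x$fp, x$fn, x$tn,
              if (length(x$flags)) paste0("  [flagged 0: ",
                                          paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.gaze_metrics <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn, accuracy = x$accuracy,
             precision = x$precision, recall = x$recall, f1 = x$f1)
}
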