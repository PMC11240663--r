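#' Build a 3x3 confusion matrix
#'
#' Rows are the labelled (video-observed) classes, columns the model
#' predictions, in the fixed order sit, stand, walk.
#'
#' @param true_labels,predicted_labels Equal-length class sequences with
#'   values in sit/stand/walk.
#' @return Integer matrix of class `confusion3` with dimnames
#'   `labelled`/`predicted`.
#' @export
confusion <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    abort_typed("LengthMismatch", "label sequences differ in length")
  if (length(true_labels) < 1) abort_typed("EmptyInput", "no labels")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), BEHAVIOURS)
  if (length(bad))
    abort_typed("UnknownClass", paste("unknown class(es):", paste(bad, collapse = ", ")))
  cm <- table(factor(true_labels, levels = BEHAVIOURS),
              factor(predicted_labels, levels = BEHAVIOURS))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(labelled = BEHAVIOURS, predicted = BEHAVIOURS))
  class(cm) <- c("confusion3", class(cm))
  cm
}

#' Wrap a printed 3x3 count matrix as a confusion matrix
#' @param counts 3x3 matrix of counts, rows = labelled sit/stand/walk,
#'   columns = predicted sit/stand/walk.
#' @return A `confusion3` matrix.
#' @export
as_confusion3 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3)))
    abort_typed("BadMatrix", "expected a 3x3 count matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    abort_typed("BadMatrix", "counts must be non-negative integers")
  cm <- matrix(as.integer(counts), 3, 3,
               dimnames = list(labelled = BEHAVIOURS, predicted = BEHAVIOURS))
  class(cm) <- c("confusion3", class(cm))
  cm
}

# One-vs-rest TP / FN / FP / TN for one class of a confusion3 matrix.
ovr_counts <- function(cm, cls) {
  i <- match(cls, BEHAVIOURS)
  if (is.na(i)) abort_typed("UnknownClass", paste("unknown class:", cls))
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

metrics_from_counts <- function(cnt) {
  rate <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tp <- cnt[["TP"]]; fn <- cnt[["FN"]]; fp <- cnt[["FP"]]; tn <- cnt[["TN"]]
  c(accuracy = rate(tp + tn, tp + tn + fp + fn),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    precision = rate(tp, tp + fp))
}

#' Per-class evaluation metrics
#'
#' One-vs-rest TP/FN/FP/TN for the class, then
#' accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), precision = TP/(TP+FP), each as a percent.
#' A zero denominator yields `NA` (undefined metric), not an error.
#'
#' @param cm A `confusion3` matrix.
#' @param cls One of `"sit"`, `"stand"`, `"walk"`.
#' @param rounded Round half-up to integer percent (the display convention)?
#'   Default `FALSE` (full precision).
#' @return Named numeric vector
#'   `(accuracy, sensitivity, specificity, precision)` in percent.
#' @export
class_metrics <- function(cm, cls, rounded = FALSE) {
  m <- metrics_from_counts(ovr_counts(cm, cls))
  if (rounded) round_half_up(m) else m
}

#' Overall (micro-aggregated) evaluation metrics
#'
#' Class-wise one-vs-rest TP, FN, FP and TN are summed over the three classes
#' and the four metric formulas applied to the sums. This micro-aggregation
#' weights each class by its support, so the dominant behaviour (typically
#' sitting) carries the most weight; it also makes overall sensitivity and
#' precision both equal `trace(cm)/n`.
#'
#' @inheritParams class_metrics
#' @return Named numeric vector
#'   `(accuracy, sensitivity, specificity, precision)` in percent.
#' @export
overall_metrics <- function(cm, rounded = FALSE) {
  tot <- Reduce(`+`, lapply(BEHAVIOURS, function(cl) ovr_counts(cm, cl)))
  m <- metrics_from_counts(tot)
  if (rounded) round_half_up(m) else m
}

#' Full metrics report for a confusion matrix
#'
#' One row per class plus the micro-aggregated overall row, with accuracy,
#' sensitivity, specificity and precision in percent.
#'
#' @inheritParams class_metrics
#' @return data.frame of class `metrics_report` with columns `class`,
#'   `accuracy`, `sensitivity`, `specificity`, `precision`.
#' @export
metrics_report <- function(cm, rounded = FALSE) {
  rows <- rbind(
    do.call(rbind, lapply(BEHAVIOURS, function(cl) class_metrics(cm, cl, rounded))),
    overall_metrics(cm, rounded))
  out <- data.frame(class = c(BEHAVIOURS, "overall"), rows,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  # shading convention of the result tables: >= 80 plain, 60-79 '+', <= 59 '*'
  shade <- function(v) ifelse(is.na(v), "  NA",
                       sprintf("%4.0f%s", v, ifelse(v >= 80, " ", ifelse(v >= 60, "+", "*"))))
  cat(sprintf("%-8s %9s %12s %12s %10s\n", "class", "accuracy", "sensitivity",
              "specificity", "precision"))
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-8s %9s %12s %12s %10s\n", x$class[i],
                shade(x$accuracy[i]), shade(x$sensitivity[i]),
                shade(x$specificity[i]), shade(x$precision[i])))
  invisible(x)
}
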