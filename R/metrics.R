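# Confusion-count bookkeeping and the four evaluation metrics
# (precision, recall, F1, accuracy), with one-vs-rest reduction and macro
# averaging for multi-class problems.

#' Confusion counts from label sequences
#'
#' Standard one-vs-rest tally of true/false positives/negatives for a chosen
#' positive class.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param positive The label treated as positive.
#' @return Object of class `"confusion_counts"`: list with `tp`, `tn`, `fp`,
#'   `fn`.
#' @examples
#' confusion_from_predictions(c(1,1,0,0), c(1,0,0,0), positive = 1)
#' @export
confusion_from_predictions <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted))
    stopf("truth and predicted must have equal length (%d vs %d)",
          length(truth), length(predicted))
  t_pos <- truth == positive
  p_pos <- predicted == positive
  confusion_counts(tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
                   fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos))
}

#' Construct confusion counts directly
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return Object of class `"confusion_counts"`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != floor(v))) stopf("counts must be non-negative integers")
  v <- as.list(v)
  structure(lapply(v, as.integer), class = "confusion_counts")
}

#' Precision, recall, F1 and accuracy from confusion counts
#'
#' Prec = TP/(TP+FP); Rec = TP/(TP+FN); F1 = 2*Prec*Rec/(Prec+Rec);
#' Acc = (TP+TN)/(TP+TN+FP+FN). A ratio with zero denominator is reported as
#' 0 and flagged in `degenerate` rather than raising, so batch evaluation
#' never aborts.
#'
#' @param counts A `"confusion_counts"` object.
#' @return Object of class `"metrics_report"`: list with `precision`,
#'   `recall`, `f1`, `accuracy` and a character vector `degenerate` naming
#'   any zero-denominator metrics.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  degen <- character()
  ratio <- function(num, den, what) {
    if (den == 0) { degen <<- c(degen, what); 0 } else num / den
  }
  prec <- ratio(counts$tp, counts$tp + counts$fp, "precision")
  rec <- ratio(counts$tp, counts$tp + counts$fn, "recall")
  f1 <- ratio(2 * prec * rec, prec + rec, "f1")
  acc <- ratio(counts$tp + counts$tn,
               counts$tp + counts$tn + counts$fp + counts$fn, "accuracy")
  structure(list(precision = prec, recall = rec, f1 = f1, accuracy = acc,
                 degenerate = degen),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("precision %.4f  recall %.4f  F1 %.4f  accuracy %.4f\n",
              x$precision, x$recall, x$f1, x$accuracy))
  if (length(x$degenerate))
    cat("  (degenerate, reported as 0:", paste(x$degenerate, collapse = ", "), ")\n")
  invisible(x)
}

#' Per-class and macro-averaged metrics for multi-class predictions
#'
#' Reduces a multi-class problem to one one-vs-rest confusion table per
#' class, computes the four metrics for each, and macro-averages them
#' (the unweighted mean over classes).
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Class labels to evaluate; defaults to the sorted union of
#'   observed labels.
#' @return A data.frame with one row per class plus a final `"macro"` row,
#'   columns `class`, `precision`, `recall`, `f1`, `accuracy`.
#' @export
evaluate_predictions <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  rows <- lapply(classes, function(cl) {
    m <- compute_metrics(confusion_from_predictions(truth, predicted, cl))
    data.frame(class = as.character(cl), precision = m$precision,
               recall = m$recall, f1 = m$f1, accuracy = m$accuracy,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  macro <- data.frame(class = "macro", precision = mean(tab$precision),
                      recall = mean(tab$recall), f1 = mean(tab$f1),
                      accuracy = mean(tab$accuracy), stringsAsFactors = FALSE)
  rbind(tab, macro)
}

#' Multi-class confusion matrix
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes Row/column labels; defaults to the sorted union.
#' @return Integer matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  m <- table(factor(truth, levels = classes),
             factor(predicted, levels = classes))
  mat <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(truth = classes, predicted = classes))
  mat
}
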