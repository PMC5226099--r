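# Evaluation: confusion counts, the six headline metrics, and the ROC
# curve / AUC from a cut-off sweep.

#' Confusion counts of binary predictions
#'
#' @param labels true binary labels (1 = enhancer).
#' @param predicted predicted binary labels.
#' @return A [ConfusionCounts].
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))  # TP=1 FN=1 TN=1 FP=1
#' @export
confusionCounts <- function(labels, predicted) {
  if (length(labels) != length(predicted)) {
    stop("labels and predictions differ in length (", length(labels),
         " vs ", length(predicted), ")")
  }
  labels <- assertBinaryLabels(labels)
  predicted <- assertBinaryLabels(predicted, "predicted labels")
  new("ConfusionCounts",
      tp = sum(labels == 1L & predicted == 1L),
      fp = sum(labels == 0L & predicted == 1L),
      tn = sum(labels == 0L & predicted == 0L),
      fn = sum(labels == 1L & predicted == 0L))
}

safeRatio <- function(num, den) if (den == 0) NA_real_ else num / den

#' The six classification metrics from confusion counts
#'
#' Precision TP/(TP+FP); recall and sensitivity TP/(TP+FN); specificity
#' TN/(TN+FP); F-score 2*precision*recall/(precision+recall); accuracy
#' (TP+TN)/(TP+TN+FP+FN). A metric whose denominator is zero is
#' *undefined* and reported as `NA` rather than an error; the F-score is
#' undefined whenever precision or recall is (or both are 0).
#'
#' @param counts a [ConfusionCounts].
#' @return A [MetricsReport].
#' @export
classifierMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  precision <- safeRatio(tp, tp + fp)
  recall <- safeRatio(tp, tp + fn)
  specificity <- safeRatio(tn, tn + fp)
  fScore <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  accuracy <- safeRatio(tp + tn, tp + tn + fp + fn)
  new("MetricsReport", counts = counts, precision = precision,
      recall = recall, specificity = specificity, sensitivity = recall,
      fScore = fScore, accuracy = accuracy)
}

#' ROC curve and AUC from a cut-off sweep
#'
#' Sweeps the classification cut-off over every distinct score (tied
#' scores collapse to a single threshold step), accumulating
#' (FPR, TPR) = (1 - specificity, sensitivity) points from (0,0) to
#' (1,1), and integrates the area under the curve with the trapezoidal
#' rule. With ties handled this way the trapezoidal AUC equals the
#' Mann-Whitney pairwise statistic
#' (#\{pos > neg\} + 0.5 #\{ties\}) / (n_pos * n_neg).
#'
#' @param labels binary labels with both classes present.
#' @param scores real-valued classifier scores (higher = more enhancer-like).
#' @return A [RocCurve].
#' @export
rocCurve <- function(labels, scores) {
  labels <- assertBothClasses(labels)
  if (length(scores) != length(labels)) {
    stop("labels and scores differ in length")
  }
  if (anyNA(scores)) stop("scores must not contain missing values")
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # last index of each distinct score: one ROC point per threshold
  stepEnd <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(l == 1L)[stepEnd]
  fp <- cumsum(l == 0L)[stepEnd]
  fpr <- c(0, fp / nNeg)
  tpr <- c(0, tp / nPos)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  new("RocCurve", fpr = fpr, tpr = tpr,
      thresholds = c(Inf, s[stepEnd]), auc = auc)
}

#' Write ROC curve points as tab-separated text
#'
#' @param roc a [RocCurve].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRocPoints <- function(roc, path) {
  stopifnot(is(roc, "RocCurve"))
  write.table(
    data.frame(threshold = roc@thresholds, fpr = roc@fpr, tpr = roc@tpr),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
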