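#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @import SummarizedExperiment
#' @importFrom GenomeInfoDb seqlevels keepSeqlevels seqlengths seqlengths<-
#'   sortSeqlevels
#' @importFrom Biostrings DNAString DNAStringSet oligonucleotideFrequency
#'   readDNAStringSet writeXStringSet mkAllStrings
#' @importFrom stats kmeans predict rlnorm runif setNames
#' @importFrom utils read.table write.table
NULL

# ---------------------------------------------------------------------------
# WindowGrid: the fixed-width tiling of a genome into prediction units
# ---------------------------------------------------------------------------

#' WindowGrid: fixed-width genomic bins
#'
#' A `WindowGrid` tiles every chromosome of a genome from position 0 into
#' consecutive, non-overlapping bins of a fixed width (200 bp by default,
#' the working resolution of preprocessed histone-modification data).
#' A chromosome whose length is not a multiple of the width keeps a final
#' truncated bin, so the tiling is a lossless partition of the genome.
#'
#' @slot windows a [GenomicRanges::GRanges] of the bins, sorted, one
#'   chromosome after another.
#' @slot chromSizes named integer vector of chromosome lengths (bp).
#' @slot binWidth bin width in bp.
#' @seealso [makeWindows()]
#' @aliases WindowGrid
#' @export
setClass("WindowGrid",
  representation(windows = "GRanges", chromSizes = "integer",
                 binWidth = "integer"))

setValidity("WindowGrid", function(object) {
  w <- object@windows
  msgs <- character()
  if (object@binWidth < 1L) msgs <- c(msgs, "binWidth must be >= 1")
  if (is.null(names(object@chromSizes)) || any(!nzchar(names(object@chromSizes))))
    msgs <- c(msgs, "chromSizes must be named")
  if (any(object@chromSizes < 1L)) msgs <- c(msgs, "chromosome lengths must be >= 1")
  expected <- sum(ceiling(object@chromSizes / object@binWidth))
  if (length(w) != expected)
    msgs <- c(msgs, sprintf("expected %d windows, found %d", expected, length(w)))
  if (length(w) && max(width(w)) > object@binWidth)
    msgs <- c(msgs, "windows wider than binWidth")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn WindowGrid number of bins in the grid.
#' @param x,object a `WindowGrid`.
#' @export
setMethod("length", "WindowGrid", function(x) length(x@windows))

setMethod("show", "WindowGrid", function(object) {
  cat(sprintf("WindowGrid: %d windows of %d bp over %d chromosome(s) (%s bp)\n",
              length(object), object@binWidth, length(object@chromSizes),
              format(sum(as.numeric(object@chromSizes)), big.mark = ",")))
})

# ---------------------------------------------------------------------------
# EnhancerDataset: per-window features + binary labels for one tissue
# ---------------------------------------------------------------------------

#' EnhancerDataset: per-window feature matrix plus enhancer labels
#'
#' A thin extension of [SummarizedExperiment::RangedSummarizedExperiment]
#' holding one tissue's window-level data: rows are genomic windows
#' (`rowRanges`), columns are features (histone marks or k-mers), the
#' single assay `"signal"` is the raw feature matrix, and
#' `rowData(x)$label` carries the binary enhancer label (1 = enhancer).
#' The tissue or cell-line name lives in `metadata(x)$tissue`.
#'
#' @aliases EnhancerDataset
#' @seealso [buildDataset()], [enhancerDataset()]
#' @export
setClass("EnhancerDataset", contains = "RangedSummarizedExperiment")

setValidity("EnhancerDataset", function(object) {
  msgs <- character()
  if (!"signal" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'signal' is required")
  lab <- rowData(object)$label
  if (is.null(lab)) {
    msgs <- c(msgs, "rowData(x)$label is required")
  } else if (anyNA(lab) || !all(lab %in% c(0L, 1L))) {
    msgs <- c(msgs, "labels must be binary 0/1")
  }
  if (anyNA(assay(object, "signal")))
    msgs <- c(msgs, "feature matrix must not contain missing values")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EnhancerDataset
#'
#' @param features numeric matrix, windows x features, no missing values.
#'   Absent signal is encoded as 0, not `NA`.
#' @param labels binary 0/1 vector, one per window.
#' @param windows [GenomicRanges::GRanges] of the windows (rows).
#' @param tissue tissue / cell-line name.
#' @return An [EnhancerDataset].
#' @export
enhancerDataset <- function(features, labels, windows, tissue = "tissue") {
  features <- as.matrix(features)
  labels <- assertBinaryLabels(labels)
  stopifnot(nrow(features) == length(labels),
            nrow(features) == length(windows))
  se <- SummarizedExperiment(
    assays = list(signal = features),
    rowRanges = windows,
    colData = DataFrame(row.names = colnames(features)))
  rowData(se)$label <- labels
  S4Vectors::metadata(se)$tissue <- tissue
  new("EnhancerDataset", se)
}

#' @importFrom SummarizedExperiment assayNames rowData rowData<-
NULL

setMethod("show", "EnhancerDataset", function(object) {
  lab <- rowData(object)$label
  cat(sprintf(
    "EnhancerDataset '%s': %d windows x %d features (%d positive, %.2f%%)\n",
    tissueName(object), nrow(object), ncol(object), sum(lab),
    100 * mean(lab)))
  cat("features:", paste(markNames(object), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# Evaluation containers
# ---------------------------------------------------------------------------

#' ConfusionCounts: the four cells of a binary confusion matrix
#'
#' @slot tp,fp,tn,fn non-negative integer counts.
#' @aliases ConfusionCounts
#' @seealso [confusionCounts()]
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", tn = "integer", fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(v) != 4L || anyNA(v) || any(v < 0L)) "counts must be non-negative scalars"
  else TRUE
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              object@tp, object@fp, object@tn, object@fn,
              object@tp + object@fp + object@tn + object@fn))
})

#' MetricsReport: the six headline classification metrics
#'
#' Precision, recall, specificity, sensitivity, F-score and accuracy
#' derived from a [ConfusionCounts]. A metric whose denominator is zero
#' is *undefined* and stored as `NA`; recall and sensitivity are the same
#' quantity and always agree.
#'
#' @slot counts the underlying [ConfusionCounts].
#' @slot precision,recall,specificity,sensitivity,fScore,accuracy numeric
#'   in \[0,1\] or `NA` when undefined.
#' @aliases MetricsReport
#' @seealso [classifierMetrics()]
#' @export
setClass("MetricsReport",
  representation(counts = "ConfusionCounts", precision = "numeric",
                 recall = "numeric", specificity = "numeric",
                 sensitivity = "numeric", fScore = "numeric",
                 accuracy = "numeric"))

setValidity("MetricsReport", function(object) {
  v <- c(object@precision, object@recall, object@specificity,
         object@sensitivity, object@fScore, object@accuracy)
  ok <- is.na(v) | (v >= 0 & v <= 1)
  if (!all(ok)) return("defined metrics must lie in [0,1]")
  if (!identical(is.na(object@recall), is.na(object@sensitivity)) ||
      (!is.na(object@recall) && object@recall != object@sensitivity))
    return("recall and sensitivity must agree")
  TRUE
})

setMethod("show", "MetricsReport", function(object) {
  fmt <- function(x) ifelse(is.na(x), "undefined", sprintf("%.4f", x))
  cat("MetricsReport\n")
  cat(sprintf("  precision:   %s\n  recall:      %s\n  specificity: %s\n",
              fmt(object@precision), fmt(object@recall), fmt(object@specificity)))
  cat(sprintf("  sensitivity: %s\n  F-score:     %s\n  accuracy:    %s\n",
              fmt(object@sensitivity), fmt(object@fScore), fmt(object@accuracy)))
})

#' RocCurve: cut-off sweep ROC points and the area under them
#'
#' @slot fpr,tpr coordinates of the curve, starting at (0,0) and ending at
#'   (1,1), non-decreasing in both axes.
#' @slot thresholds the score cut-off generating each point (`Inf` first).
#' @slot auc trapezoidal area under the curve.
#' @aliases RocCurve
#' @seealso [rocCurve()]
#' @export
setClass("RocCurve",
  representation(fpr = "numeric", tpr = "numeric", thresholds = "numeric",
                 auc = "numeric"))

setValidity("RocCurve", function(object) {
  msgs <- character()
  n <- length(object@fpr)
  if (length(object@tpr) != n || length(object@thresholds) != n)
    msgs <- c(msgs, "fpr/tpr/thresholds lengths differ")
  if (n < 2 || object@fpr[1] != 0 || object@tpr[1] != 0 ||
      object@fpr[n] != 1 || object@tpr[n] != 1)
    msgs <- c(msgs, "curve must run from (0,0) to (1,1)")
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
    msgs <- c(msgs, "curve must be monotone non-decreasing")
  if (object@auc < 0 || object@auc > 1) msgs <- c(msgs, "auc must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d points, AUC = %.4f\n",
              length(object@fpr), object@auc))
})

# ---------------------------------------------------------------------------
# Models
# ---------------------------------------------------------------------------

#' BaseForest: one tissue's random-forest base classifier
#'
#' Holds the forest trained on the 60% training portion of a balanced
#' tissue dataset, the min-max normalization fitted on that portion, and
#' the held-out 40% windows with the F-score measured on them. The
#' held-out windows are retained because the meta-classifier is trained
#' on the pooled held-out windows of all tissues.
#'
#' @slot tissue tissue / cell-line name.
#' @slot forest the fitted [randomForest::randomForest] object.
#' @slot markNames feature columns the forest was trained on, in order.
#' @slot normFit per-column min/max fitted on the training portion.
#' @slot heldoutFscore F-score on the held-out portion at cut-off 0.5
#'   (0 when undefined, i.e. no predicted positives).
#' @slot heldoutReport full [MetricsReport] on the held-out portion.
#' @slot heldoutFeatures raw (unnormalized) held-out feature matrix.
#' @slot heldoutLabels held-out labels.
#' @slot config the [forestConfig()] used.
#' @aliases BaseForest
#' @seealso [trainBaseForest()], [confidenceScores()]
#' @export
setClass("BaseForest",
  representation(tissue = "character", forest = "ANY", markNames = "character",
                 normFit = "list", heldoutFscore = "numeric",
                 heldoutReport = "MetricsReport", heldoutFeatures = "matrix",
                 heldoutLabels = "integer", config = "list"))

setValidity("BaseForest", function(object) {
  msgs <- character()
  if (object@heldoutFscore < 0 || object@heldoutFscore > 1)
    msgs <- c(msgs, "heldoutFscore must lie in [0,1]")
  if (!is.null(object@forest$ntree) &&
      object@forest$ntree != object@config$nTrees)
    msgs <- c(msgs, "forest must have exactly nTrees trees")
  if (ncol(object@heldoutFeatures) != length(object@markNames))
    msgs <- c(msgs, "held-out features must match markNames")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "BaseForest", function(object) {
  cat(sprintf(
    "BaseForest '%s': %d trees on %d features; held-out F-score = %.4f (n=%d)\n",
    object@tissue, object@forest$ntree, length(object@markNames),
    object@heldoutFscore, length(object@heldoutLabels)))
})

#' MetaDataset: stacked meta-features for the main classifier
#'
#' Entry (i, j) is base classifier j's confidence score on window i
#' multiplied by that classifier's held-out F-score, so every entry lies
#' in \[0,1\] and column j is bounded above by F-score j.
#'
#' @slot metaFeatures numeric matrix, windows x base classifiers.
#' @slot labels binary labels for the windows.
#' @slot baseNames tissue names of the base classifiers (column order).
#' @aliases MetaDataset
#' @seealso [buildMetaFeatures()]
#' @export
setClass("MetaDataset",
  representation(metaFeatures = "matrix", labels = "integer",
                 baseNames = "character"))

setValidity("MetaDataset", function(object) {
  msgs <- character()
  if (nrow(object@metaFeatures) != length(object@labels))
    msgs <- c(msgs, "one label per row is required")
  if (ncol(object@metaFeatures) != length(object@baseNames))
    msgs <- c(msgs, "one base name per column is required")
  m <- object@metaFeatures
  if (length(m) && (anyNA(m) || min(m) < 0 || max(m) > 1))
    msgs <- c(msgs, "meta-features must lie in [0,1]")
  if (!all(object@labels %in% c(0L, 1L)))
    msgs <- c(msgs, "labels must be binary 0/1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MetaDataset", function(object) {
  cat(sprintf("MetaDataset: %d windows x %d base classifiers (%s); %d positive\n",
              nrow(object@metaFeatures), length(object@baseNames),
              paste(object@baseNames, collapse = ", "), sum(object@labels)))
})

#' MetaSVM: the RBF-SVM main classifier
#'
#' @slot model fitted [e1071::svm] with an RBF kernel.
#' @slot chosenC,chosenGamma the grid-search winners.
#' @slot cvBalancedError mean 10-fold CV balanced error rate of the winner.
#' @slot baseNames meta-feature column names the model expects.
#' @slot cvSurface data.frame of (C, gamma, ber) over the whole grid.
#' @aliases MetaSVM
#' @seealso [gridSearchSvm()], [predictMeta()]
#' @export
setClass("MetaSVM",
  representation(model = "ANY", chosenC = "numeric", chosenGamma = "numeric",
                 cvBalancedError = "numeric", baseNames = "character",
                 cvSurface = "data.frame"))

setValidity("MetaSVM", function(object) {
  msgs <- character()
  if (object@chosenC <= 0 || object@chosenGamma <= 0)
    msgs <- c(msgs, "chosen C and gamma must be positive")
  if (object@cvBalancedError < 0 || object@cvBalancedError > 1)
    msgs <- c(msgs, "cvBalancedError must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MetaSVM", function(object) {
  cat(sprintf(
    "MetaSVM over %d base classifiers: C = %g, gamma = %g, CV BER = %.4f\n",
    length(object@baseNames), object@chosenC, object@chosenGamma,
    object@cvBalancedError))
})

#' EnhancerStack: the full trained hybrid classifier
#'
#' Bundles the per-tissue [BaseForest] base classifiers with the
#' [MetaSVM] main classifier and the training report.
#'
#' @slot baseModels named list of [BaseForest] objects.
#' @slot metaModel the [MetaSVM].
#' @slot markNames feature columns shared by all base models.
#' @slot binWidth window width (bp) the stack was trained at.
#' @slot trainReport per-classifier training metrics.
#' @slot manifest provenance: configs, seed and input checksums.
#' @aliases EnhancerStack
#' @seealso [fitEnhancerStack()], [predictEnhancers()]
#' @export
setClass("EnhancerStack",
  representation(baseModels = "list", metaModel = "MetaSVM",
                 markNames = "character", binWidth = "integer",
                 trainReport = "data.frame", manifest = "list"))

setValidity("EnhancerStack", function(object) {
  msgs <- character()
  if (length(object@baseModels) < 2L)
    msgs <- c(msgs, "a stack needs at least 2 base models")
  if (!all(vapply(object@baseModels, is, logical(1), "BaseForest")))
    msgs <- c(msgs, "baseModels must all be BaseForest objects")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "EnhancerStack", function(object) {
  cat(sprintf("EnhancerStack: %d base forests (%s) under an RBF-SVM\n",
              length(object@baseModels),
              paste(names(object@baseModels), collapse = ", ")))
  cat(sprintf("  marks: %s\n  meta: C = %g, gamma = %g, CV BER = %.4f\n",
              paste(object@markNames, collapse = ", "),
              object@metaModel@chosenC, object@metaModel@chosenGamma,
              object@metaModel@cvBalancedError))
})
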