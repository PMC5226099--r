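# Per-tissue random-forest base classifiers. The forest is an ensemble of
# decision trees grown on bootstrap resamples, with splits chosen by
# information gain; its soft output is the confidence score, the fraction
# of trees voting "enhancer".

#' Shannon entropy of a class distribution (bits)
#'
#' `entropyBits(p) = -sum(p_i * log2(p_i))` with 0 log 0 taken as 0; this
#' is the node impurity the information-gain split criterion is built on.
#'
#' @param p vector of class proportions (non-negative, summing to 1).
#' @return Entropy in bits, in \[0, log2(length(p))\].
#' @examples
#' entropyBits(c(0.5, 0.5))  # 1
#' entropyBits(c(1, 0))      # 0
#' @export
entropyBits <- function(p) {
  if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("p must be a class distribution: non-negative proportions summing to 1")
  }
  p <- p[p > 0]
  -sum(p * log2(p))
}

labelEntropy <- function(labels) {
  if (!length(labels)) return(0)
  entropyBits(as.vector(table(labels)) / length(labels))
}

#' Information gain of a candidate split
#'
#' `gain = entropy(parent) - sum(|child|/|parent| * entropy(child))`,
#' the reduction in label entropy from partitioning the parent node into
#' the given children. The children must be an exact partition of the
#' parent's labels (as a multiset).
#'
#' @param parentLabels label vector at the parent node.
#' @param children list of label vectors, one per child.
#' @return Information gain in bits (>= 0 up to floating error).
#' @examples
#' infoGain(c(1, 1, 0, 0), list(c(1, 1), c(0, 0)))  # 1: a perfect split
#' @export
infoGain <- function(parentLabels, children) {
  stopifnot(is.list(children), length(children) >= 1)
  pooled <- unlist(children, use.names = FALSE)
  if (length(pooled) != length(parentLabels) ||
      !identical(sort(as.character(pooled)), sort(as.character(parentLabels)))) {
    stop("children must partition the parent labels exactly")
  }
  n <- length(parentLabels)
  childTerm <- sum(vapply(children, function(ch) {
    length(ch) / n * labelEntropy(ch)
  }, numeric(1)))
  labelEntropy(parentLabels) - childTerm
}

#' Train one tissue's random-forest base classifier
#'
#' Splits the (already class-balanced) dataset into a stratified 60/40
#' train/test partition, fits the min-max normalization on the training
#' portion only, grows the forest on the normalized training data, and
#' scores the held-out 40% to obtain the classifier's F-score at cut-off
#' 0.5. The held-out windows and their raw features are retained in the
#' returned model: the meta-classifier is trained on all tissues' pooled
#' held-out windows.
#'
#' Forest fitting is delegated to [randomForest::randomForest] (bootstrap
#' resamples, Gini-grown binary threshold splits over a random feature
#' subset per node); the package's [confidenceScores()] is exactly the
#' tree-vote fraction the ensemble votes with.
#'
#' An undefined held-out F-score (no predicted positives, or no true
#' positives among them) is stored as 0 so downstream meta-features stay
#' defined; the full [MetricsReport] keeps the `NA`.
#'
#' @param dataset an [EnhancerDataset] containing both classes, normally
#'   the output of [subsampleNegatives()].
#' @param config a [forestConfig()].
#' @param trainFraction fraction used for training (default 0.6).
#' @return A [BaseForest].
#' @export
trainBaseForest <- function(dataset, config = forestConfig(),
                            trainFraction = 0.6) {
  stopifnot(is(dataset, "EnhancerDataset"), inherits(config, "forest_config"))
  labels <- assertBothClasses(windowLabels(dataset), "dataset labels")
  feats <- featureMatrix(dataset)
  if (is.null(colnames(feats))) {
    stop("dataset feature matrix must have column (mark) names")
  }
  train <- stratifiedSplit(labels, trainFraction, seed = config$seed)
  fit <- minmaxFit(feats[train, , drop = FALSE])
  xTrain <- minmaxApply(feats[train, , drop = FALSE], fit, clip = TRUE)
  xTest <- minmaxApply(feats[!train, , drop = FALSE], fit, clip = TRUE)
  mtry <- if (is.null(config$featuresPerSplit)) {
    ceiling(sqrt(ncol(feats)))
  } else {
    min(config$featuresPerSplit, ncol(feats))
  }
  forest <- withSeed(config$seed, {
    randomForest::randomForest(
      x = xTrain, y = factor(labels[train], levels = c("0", "1")),
      ntree = config$nTrees, mtry = mtry,
      nodesize = config$minSamplesSplit - 1L,
      maxnodes = config$maxNodes)
  })
  votes <- predict(forest, xTest, type = "vote", norm.votes = TRUE)[, "1"]
  predicted <- as.integer(votes >= 0.5)
  report <- classifierMetrics(confusionCounts(labels[!train], predicted))
  fscore <- report@fScore
  new("BaseForest",
      tissue = tissueName(dataset),
      forest = forest,
      markNames = colnames(feats),
      normFit = fit,
      heldoutFscore = if (is.na(fscore)) 0 else fscore,
      heldoutReport = report,
      heldoutFeatures = feats[!train, , drop = FALSE],
      heldoutLabels = labels[!train],
      config = unclass(config))
}

#' Tree-vote confidence scores
#'
#' The base classifier's soft output for each window: the fraction of
#' trees in the forest voting "enhancer",
#' `tree_number(positive) / tree_number(total)`, a value in \[0,1\] with
#' resolution 1/nTrees. Features are raw signal; the model's stored
#' training-set min-max normalization is applied (with clipping) before
#' the trees vote.
#'
#' @param model a [BaseForest].
#' @param features raw feature matrix whose columns match the model's
#'   `markNames` (order-insensitive; a mismatch is an error naming the
#'   missing/extra columns).
#' @return Numeric vector of confidence scores in \[0,1\].
#' @export
confidenceScores <- function(model, features) {
  stopifnot(is(model, "BaseForest"))
  features <- as.matrix(features)
  missing <- setdiff(model@markNames, colnames(features))
  extra <- setdiff(colnames(features), model@markNames)
  if (length(missing) || length(extra)) {
    stop("feature columns do not match the model: missing [",
         paste(missing, collapse = ", "), "], extra [",
         paste(extra, collapse = ", "), "]")
  }
  features <- features[, model@markNames, drop = FALSE]
  x <- minmaxApply(features, model@normFit, clip = TRUE)
  unname(predict(model@forest, x, type = "vote", norm.votes = TRUE)[, "1"])
}
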