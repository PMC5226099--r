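# The main classifier: an RBF-kernel soft-margin SVM stacked on top of
# the base forests. Its inputs are meta-features
# confidence_score_j(window) * heldout_Fscore_j, so a base classifier's
# votes are weighted by how well it performed on its own held-out data.

#' Build the meta-feature matrix from base classifiers
#'
#' Every window is scored by *all* base models (the only construction
#' that yields a complete matrix when windows are pooled across tissues);
#' entry (i, j) is model j's confidence score on window i times model j's
#' held-out F-score.
#'
#' @param baseModels list of at least two [BaseForest] models.
#' @param features raw feature matrix of the windows to score; columns
#'   must match every model's `markNames`.
#' @param labels binary labels for the windows.
#' @return A [MetaDataset].
#' @export
buildMetaFeatures <- function(baseModels, features, labels) {
  if (length(baseModels) < 2L) {
    stop("stacking needs at least 2 base models")
  }
  stopifnot(all(vapply(baseModels, is, logical(1), "BaseForest")))
  labels <- assertBinaryLabels(labels)
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  baseNames <- unname(vapply(baseModels, tissueName, character(1)))
  meta <- vapply(baseModels, function(m) {
    confidenceScores(m, features) * heldoutFscore(m)
  }, numeric(nrow(features)))
  meta <- matrix(meta, nrow = nrow(features),
                 dimnames = list(NULL, baseNames))
  new("MetaDataset", metaFeatures = meta, labels = labels,
      baseNames = baseNames)
}

#' Pool held-out windows of several base models
#'
#' Concatenates the 40% held-out portions (raw features + labels) stored
#' in each [BaseForest]; this pooled set is the meta-classifier's
#' training data.
#'
#' @param baseModels list of [BaseForest] models sharing one feature set.
#' @return List with `features` (matrix) and `labels`.
#' @export
pooledHeldout <- function(baseModels) {
  stopifnot(length(baseModels) >= 1,
            all(vapply(baseModels, is, logical(1), "BaseForest")))
  list(features = do.call(rbind, lapply(baseModels, function(m) m@heldoutFeatures)),
       labels = unlist(lapply(baseModels, function(m) m@heldoutLabels),
                       use.names = FALSE))
}

#' RBF kernel value
#'
#' `k(x, x') = exp(-gamma * ||x - x'||^2)`; symmetric, in (0, 1], and 1
#' exactly when the points coincide.
#'
#' @param x,y numeric vectors of equal dimension.
#' @param gamma kernel width parameter, > 0.
#' @return Scalar kernel value.
#' @examples
#' rbfKernel(0, 1, gamma = 1)  # exp(-1)
#' @export
rbfKernel <- function(x, y, gamma) {
  if (length(x) != length(y)) stop("x and y must have the same dimension")
  stopifnot(gamma > 0)
  exp(-gamma * sum((x - y)^2))
}

#' Balanced error rate
#'
#' `BER = 1 - (sensitivity + specificity) / 2`: the grid-search selection
#' criterion, insensitive to class imbalance (a degenerate all-one-class
#' predictor scores 0.5).
#'
#' @param labels true binary labels, both classes present.
#' @param predicted predicted binary labels.
#' @return BER in \[0,1\].
#' @export
balancedErrorRate <- function(labels, predicted) {
  labels <- assertBothClasses(labels)
  counts <- confusionCounts(labels, predicted)
  sens <- counts@tp / (counts@tp + counts@fn)
  spec <- counts@tn / (counts@tn + counts@fp)
  1 - (sens + spec) / 2
}

svmFactor <- function(labels) factor(labels, levels = c("0", "1"))

fitRbfSvm <- function(x, labels, C, gamma, tolerance = 1e-3) {
  e1071::svm(x = x, y = svmFactor(labels), kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE,
             tolerance = tolerance)
}

# decision values oriented so positive = class "1"
svmDecision <- function(model, x) {
  pred <- predict(model, x, decision.values = TRUE)
  d <- attr(pred, "decision.values")
  stopifnot(ncol(d) == 1L)
  firstClass <- strsplit(colnames(d), "/", fixed = TRUE)[[1]][1]
  if (firstClass == "1") as.numeric(d) else -as.numeric(d)
}

#' Grid search for the RBF-SVM main classifier
#'
#' For every (C, gamma) pair on the configured grid, measures the mean
#' balanced error rate over seeded stratified k-fold cross-validation
#' (default 10-fold), picks the pair with the lowest CV BER (ties broken
#' toward the smallest C, then the smallest gamma - the least complex
#' model), and refits it on the full meta-dataset.
#'
#' @param meta a [MetaDataset] with both classes and at least `nFolds`
#'   samples per class.
#' @param config an [svmConfig()].
#' @return A [MetaSVM]; its `cvSurface` slot holds the full (C, gamma,
#'   BER) grid for inspection.
#' @export
gridSearchSvm <- function(meta, config = svmConfig()) {
  stopifnot(is(meta, "MetaDataset"), inherits(config, "svm_config"))
  labels <- assertBothClasses(meta@labels, "meta labels")
  x <- meta@metaFeatures
  if (nrow(x) < config$nFolds) {
    stop("need at least nFolds samples for cross-validation")
  }
  folds <- stratifiedFolds(labels, config$nFolds, seed = config$seed)
  grid <- expand.grid(gamma = config$gammaGrid, C = config$cGrid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$C, grid$gamma), c("C", "gamma")]
  ber <- vapply(seq_len(nrow(grid)), function(i) {
    foldBer <- vapply(seq_len(config$nFolds), function(f) {
      inFold <- folds == f
      model <- fitRbfSvm(x[!inFold, , drop = FALSE], labels[!inFold],
                         C = grid$C[i], gamma = grid$gamma[i],
                         tolerance = config$tolerance)
      pred <- as.integer(as.character(
        predict(model, x[inFold, , drop = FALSE])))
      balancedErrorRate(labels[inFold], pred)
    }, numeric(1))
    mean(foldBer)
  }, numeric(1))
  bestIdx <- which.min(ber)  # grid ordered by (C, gamma): ties -> smallest
  best <- grid[bestIdx, ]
  final <- fitRbfSvm(x, labels, C = best$C, gamma = best$gamma,
                     tolerance = config$tolerance)
  new("MetaSVM", model = final, chosenC = best$C, chosenGamma = best$gamma,
      cvBalancedError = ber[bestIdx], baseNames = meta@baseNames,
      cvSurface = data.frame(C = grid$C, gamma = grid$gamma, ber = ber,
                             row.names = NULL))
}

#' Predict with the meta-classifier
#'
#' Applies the decision function f(x) = sgn(w' phi(x) + b): scores are
#' the (oriented) SVM decision values, suitable for ROC analysis, and the
#' predicted label is 1 exactly when the score is positive.
#'
#' @param model a [MetaSVM].
#' @param meta a [MetaDataset] or a meta-feature matrix whose columns
#'   match the model's `baseNames`.
#' @return List with `scores` (decision values) and `labels` (0/1).
#' @export
predictMeta <- function(model, meta) {
  stopifnot(is(model, "MetaSVM"))
  x <- if (is(meta, "MetaDataset")) meta@metaFeatures else as.matrix(meta)
  if (!identical(colnames(x), model@baseNames)) {
    stop("meta-feature columns [", paste(colnames(x), collapse = ", "),
         "] do not match the model's base classifiers [",
         paste(model@baseNames, collapse = ", "), "]")
  }
  scores <- svmDecision(model@model, x)
  list(scores = scores, labels = as.integer(scores > 0))
}

#' Write the CV balanced-error surface as tab-separated text
#'
#' @param model a [MetaSVM].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCvSurface <- function(model, path) {
  stopifnot(is(model, "MetaSVM"))
  write.table(model@cvSurface, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
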