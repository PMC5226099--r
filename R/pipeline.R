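# Orchestration: train the per-tissue base forests, stack them under the
# RBF-SVM, predict on a new tissue, evaluate. The ENCODE-style and
# FANTOM5-style workflows differ only in inputs and labels, so there is
# one pipeline with the feature mode ("signal" or "kmer") as config.

deriveSeed <- function(seed, offset) (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max

#' Fit the full hybrid classifier from in-memory datasets
#'
#' For each tissue: sub-sample negatives to the configured ratio
#' ([subsampleNegatives()]), train a base forest on a stratified 60/40
#' split ([trainBaseForest()]). Then pool every tissue's held-out 40%,
#' score the pooled windows with *all* base models to build the
#' meta-feature matrix ([buildMetaFeatures()]), and grid-search the
#' RBF-SVM main classifier ([gridSearchSvm()]).
#'
#' Per-stage seeds are derived from the single top-level `seed`, so a
#' rerun with the same inputs and seed reproduces the stack exactly.
#'
#' @param datasets named list (>= 2) of [EnhancerDataset] objects sharing
#'   one feature set.
#' @param sampling a [samplingConfig()].
#' @param forest a [forestConfig()].
#' @param svm an [svmConfig()].
#' @param trainFraction base-classifier training fraction (default 0.6).
#' @param seed top-level integer seed.
#' @return An [EnhancerStack].
#' @export
fitEnhancerStack <- function(datasets,
                             sampling = samplingConfig(),
                             forest = forestConfig(),
                             svm = svmConfig(),
                             trainFraction = 0.6,
                             seed = 1L) {
  if (!is.list(datasets) || length(datasets) < 2L) {
    stop("stacking needs at least 2 training tissues; got ",
         if (is.list(datasets)) length(datasets) else 1L,
         ". Train/test on a single tissue is not a stacked design.")
  }
  stopifnot(all(vapply(datasets, is, logical(1), "EnhancerDataset")))
  markSets <- lapply(datasets, markNames)
  if (!all(vapply(markSets, identical, logical(1), markSets[[1]]))) {
    stop("all tissues must share the same feature (mark) columns")
  }
  models <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    sampling_i <- sampling; sampling_i$seed <- deriveSeed(seed, 100L * i)
    forest_i <- forest; forest_i$seed <- deriveSeed(seed, 100L * i + 1L)
    balanced <- subsampleNegatives(ds, sampling_i)
    models[[i]] <- trainBaseForest(balanced, forest_i,
                                   trainFraction = trainFraction)
  }
  names(models) <- vapply(models, tissueName, character(1))
  pooled <- pooledHeldout(models)
  meta <- buildMetaFeatures(models, pooled$features, pooled$labels)
  svm_cfg <- svm; svm_cfg$seed <- deriveSeed(seed, 7L)
  metaModel <- gridSearchSvm(meta, svm_cfg)
  report <- do.call(rbind, lapply(models, function(m) {
    cbind(data.frame(classifier = tissueName(m), role = "base"),
          as.data.frame(heldoutReport(m)))
  }))
  report <- rbind(report, data.frame(
    classifier = "meta-svm", role = "meta", precision = NA, recall = NA,
    specificity = NA, sensitivity = NA, f_score = NA,
    accuracy = NA))
  rownames(report) <- NULL
  new("EnhancerStack", baseModels = models, metaModel = metaModel,
      markNames = markSets[[1]],
      binWidth = 0L,
      trainReport = report,
      manifest = list(seed = seed,
                      sampling = unclass(sampling),
                      forest = unclass(forest),
                      svm = unclass(svm),
                      trainFraction = trainFraction,
                      cvBalancedError = metaModel@cvBalancedError))
}

#' Score new windows with a trained stack
#'
#' Every base forest scores the supplied windows (tree-vote confidence),
#' the meta-feature matrix is assembled with the stored held-out
#' F-scores, and the SVM main classifier returns decision scores and 0/1
#' labels.
#'
#' @param stack an [EnhancerStack].
#' @param features raw feature matrix (windows x marks) matching the
#'   stack's `markNames`, or an [EnhancerDataset].
#' @return List with `scores`, `labels`, `confidence` (windows x base
#'   matrix of raw confidence scores).
#' @export
predictEnhancers <- function(stack, features) {
  stopifnot(is(stack, "EnhancerStack"))
  if (is(features, "EnhancerDataset")) features <- featureMatrix(features)
  features <- as.matrix(features)
  missing <- setdiff(markNames(stack), colnames(features))
  if (length(missing)) {
    stop("test tissue lacks mark(s) the stack was trained on: ",
         paste(missing, collapse = ", "))
  }
  conf <- vapply(baseModels(stack), function(m) {
    confidenceScores(m, features[, markNames(stack), drop = FALSE])
  }, numeric(nrow(features)))
  conf <- matrix(conf, nrow = nrow(features),
                 dimnames = list(NULL, names(baseModels(stack))))
  fscores <- vapply(baseModels(stack), heldoutFscore, numeric(1))
  meta <- sweep(conf, 2, fscores, "*")
  out <- predictMeta(metaModel(stack), meta)
  out$confidence <- conf
  out
}

readTissueDataset <- function(manifest, grid, cfg) {
  if (identical(cfg$featureMode, "kmer")) {
    buildKmerDataset(cfg$genomeFasta, manifest$labels, grid,
                     tissue = manifest$name)
  } else {
    buildDataset(manifest$marks, manifest$labels, grid,
                 tissue = manifest$name)
  }
}

checkManifestFiles <- function(cfg) {
  files <- c(cfg$chromSizes, cfg$genomeFasta,
             unlist(lapply(cfg$tissues, function(t) c(unlist(t$marks), t$labels))),
             if (!is.null(cfg$testTissue))
               c(unlist(cfg$testTissue$marks), cfg$testTissue$labels))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  invisible(files)
}

#' Train the hybrid classifier from a pipeline config
#'
#' File-level front end of [fitEnhancerStack()]: validates that every
#' manifest file exists *before* any training, builds the window grid,
#' reads each tissue's peaks and labels into datasets, fits the stack,
#' and records input checksums, configs and the seed in the returned
#' stack's manifest so a run can be reproduced exactly.
#'
#' @param config a config list from [readPipelineConfig()] (or built in
#'   code with the same shape).
#' @return An [EnhancerStack].
#' @export
trainEnhancerStack <- function(config) {
  files <- checkManifestFiles(config)
  if (length(config$tissues) < 2L) {
    stop("stacking needs at least 2 training tissues; got ",
         length(config$tissues),
         ". Add tissues or train a single base classifier directly.")
  }
  grid <- makeWindows(config$chromSizes, width = config$windowWidth)
  datasets <- lapply(config$tissues, readTissueDataset, grid = grid,
                     cfg = config)
  names(datasets) <- vapply(config$tissues, `[[`, character(1), "name")
  stack <- fitEnhancerStack(datasets,
                            sampling = config$sampling,
                            forest = config$forest,
                            svm = config$svm,
                            seed = config$seed)
  stack@binWidth <- as.integer(config$windowWidth)
  stack@manifest$featureMode <- config$featureMode
  stack@manifest$inputChecksums <- as.list(tools::md5sum(files))
  stack
}

#' Predict a test tissue from files and write BED output
#'
#' @param stack an [EnhancerStack] from [trainEnhancerStack()].
#' @param manifest test-tissue manifest: `list(name=, marks=, labels=)`
#'   (labels optional for prediction).
#' @param chromSizes named sizes or chrom.sizes path.
#' @param outBed optional path; predictions written as BED6 with
#'   confidence in the score column.
#' @param featureMode `"signal"` or `"kmer"`.
#' @param genomeFasta FASTA path (k-mer mode only).
#' @return Data.frame with window coordinates, `score` and `label`.
#' @export
predictEnhancerStack <- function(stack, manifest, chromSizes, outBed = NULL,
                                 featureMode = "signal", genomeFasta = NULL) {
  width <- if (stack@binWidth > 0L) stack@binWidth else 200L
  grid <- makeWindows(chromSizes, width = width)
  ds <- if (identical(featureMode, "kmer")) {
    features <- kmerFeatureMatrix(genomeFasta, grid)
    enhancerDataset(features, integer(length(grid)), binWindows(grid),
                    tissue = manifest$name)
  } else {
    peaks <- lapply(manifest$marks, readBroadPeak)
    enhancerDataset(mapSignal(peaks, grid), integer(length(grid)),
                    binWindows(grid), tissue = manifest$name)
  }
  pred <- predictEnhancers(stack, ds)
  win <- binWindows(grid)
  out <- data.frame(chrom = as.character(seqnames(win)),
                    start = start(win) - 1L, end = end(win),
                    score = pred$scores, label = pred$labels)
  if (!is.null(outBed)) {
    # map unbounded decision values through the logistic for the BED score
    writePredictionsBed(win, 1 / (1 + exp(-pred$scores)), pred$labels, outBed)
  }
  out
}

#' Evaluate predictions against truth labels
#'
#' Joins predictions and truth on the window id (chrom:start-end),
#' requires the two window sets to coincide, and computes the confusion
#' counts, the six metrics and the ROC/AUC.
#'
#' @param predictions data.frame with `chrom`, `start`, `end`, `score`,
#'   `label` (as returned by [predictEnhancerStack()]).
#' @param truth data.frame with `chrom`, `start`, `end`, `label`.
#' @return List with `metrics` (a [MetricsReport]) and `roc` (a
#'   [RocCurve]).
#' @export
evaluatePredictions <- function(predictions, truth) {
  key <- function(d) sprintf("%s:%d-%d", d$chrom, d$start, d$end)
  pk <- key(predictions)
  tk <- key(truth)
  if (length(setdiff(pk, tk)) || length(setdiff(tk, pk))) {
    stop(sprintf(
      "prediction and truth window sets differ: %d predicted-only, %d truth-only",
      length(setdiff(pk, tk)), length(setdiff(tk, pk))))
  }
  truthLabels <- truth$label[match(pk, tk)]
  if (length(unique(truthLabels)) < 2L) {
    stop("truth labels contain a single class; metrics and ROC need both")
  }
  list(metrics = classifierMetrics(confusionCounts(truthLabels,
                                                   predictions$label)),
       roc = rocCurve(truthLabels, predictions$score))
}

#' Save / load a trained stack
#'
#' Standard R serialization of the whole model bundle (base forests, SVM,
#' normalization fits, manifest).
#'
#' @param stack an [EnhancerStack].
#' @param path file path (.rds).
#' @return `path` (save) / the [EnhancerStack] (load).
#' @export
saveStack <- function(stack, path) {
  stopifnot(is(stack, "EnhancerStack"))
  saveRDS(stack, path)
  invisible(path)
}

#' @rdname saveStack
#' @export
loadStack <- function(path) {
  stack <- readRDS(path)
  stopifnot(is(stack, "EnhancerStack"))
  stack
}
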