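# Config constructors. Plain validated lists: they travel through YAML
# config files unchanged and keep the pipeline surface light.

#' Negative sub-sampling configuration
#'
#' @param ratio negatives retained per positive (default 10, the 1:10
#'   positive:negative ratio the pipeline balances to).
#' @param nClusters k for the k-means guiding the sub-sample (default 8).
#' @param seed integer seed for clustering and sampling.
#' @param maxIter k-means iteration cap.
#' @param nStarts k-means restarts; the run with the lowest
#'   within-cluster sum of squares is kept.
#' @return A `sampling_config` list.
#' @seealso [subsampleNegatives()]
#' @export
samplingConfig <- function(ratio = 10, nClusters = 8, seed = 1L,
                           maxIter = 100L, nStarts = 5L) {
  stopifnot(ratio >= 1, nClusters >= 1, maxIter >= 1, nStarts >= 1)
  structure(list(ratio = ratio, nClusters = as.integer(nClusters),
                 seed = seed, maxIter = as.integer(maxIter),
                 nStarts = as.integer(nStarts)),
            class = "sampling_config")
}

#' Random-forest configuration
#'
#' Standard Breiman defaults: 100 bootstrap trees, `ceiling(sqrt(p))`
#' candidate features per split, nodes grown until pure
#' (`minSamplesSplit = 2`, unlimited depth).
#'
#' @param nTrees number of bootstrap samples / trees.
#' @param featuresPerSplit candidate features per node; `NULL` means
#'   `ceiling(sqrt(n_features))`.
#' @param minSamplesSplit minimum node size still considered for a split.
#' @param maxNodes optional cap on terminal nodes (depth control);
#'   `NULL` = unlimited.
#' @param seed integer seed for the split and the bootstrap.
#' @return A `forest_config` list.
#' @seealso [trainBaseForest()]
#' @export
forestConfig <- function(nTrees = 100L, featuresPerSplit = NULL,
                         minSamplesSplit = 2L, maxNodes = NULL, seed = 1L) {
  stopifnot(nTrees >= 1, minSamplesSplit >= 2)
  structure(list(nTrees = as.integer(nTrees),
                 featuresPerSplit = featuresPerSplit,
                 minSamplesSplit = as.integer(minSamplesSplit),
                 maxNodes = maxNodes, seed = seed),
            class = "forest_config")
}

#' RBF-SVM grid-search configuration
#'
#' The default grids are C in \{2, 4, ..., 50\} and gamma in
#' \{2, 4, ..., 200\}. (The degenerate endpoints C = 0 and gamma = 0 are
#' excluded: C = 0 removes the misclassification penalty entirely and
#' gamma = 0 collapses the RBF kernel to a constant.)
#'
#' @param cGrid candidate soft-margin costs, all > 0.
#' @param gammaGrid candidate RBF widths, all > 0.
#' @param nFolds cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param tolerance solver termination tolerance.
#' @return An `svm_config` list.
#' @seealso [gridSearchSvm()]
#' @export
svmConfig <- function(cGrid = seq(2, 50, by = 2),
                      gammaGrid = seq(2, 200, by = 2),
                      nFolds = 10L, seed = 1L, tolerance = 1e-3) {
  stopifnot(all(cGrid > 0), all(gammaGrid > 0), nFolds >= 2)
  structure(list(cGrid = sort(unique(cGrid)),
                 gammaGrid = sort(unique(gammaGrid)),
                 nFolds = as.integer(nFolds), seed = seed,
                 tolerance = tolerance),
            class = "svm_config")
}

#' Read a pipeline configuration file
#'
#' Loads a YAML pipeline description: per-tissue input manifests
#' (mark -> peak file, label file), the chrom.sizes path, window width,
#' feature mode, and the `sampling:`, `forest:` and `svm:` blocks (each
#' optional, defaulted by the corresponding constructor). Relative paths
#' are resolved against the config file's directory.
#'
#' @param path YAML config path.
#' @return A named list with elements `tissues`, `testTissue` (may be
#'   `NULL`), `chromSizes`, `windowWidth`, `featureMode`, `sampling`,
#'   `forest`, `svm`, `seed`, `outDir`.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  fixTissue <- function(t) {
    list(name = t$name,
         marks = lapply(t$marks, resolve),
         labels = resolve(t$labels))
  }
  cfg <- list(
    tissues = lapply(raw$tissues, fixTissue),
    testTissue = if (!is.null(raw$test_tissue)) fixTissue(raw$test_tissue),
    chromSizes = resolve(raw$chrom_sizes),
    windowWidth = if (is.null(raw$window_width)) 200L else as.integer(raw$window_width),
    featureMode = if (is.null(raw$feature_mode)) "signal" else raw$feature_mode,
    genomeFasta = resolve(raw$genome_fasta),
    sampling = do.call(samplingConfig, as.list(raw$sampling)),
    forest = do.call(forestConfig, as.list(raw$forest)),
    svm = do.call(svmConfig, c(
      if (!is.null(raw$svm$c_grid)) list(cGrid = unlist(raw$svm$c_grid)),
      if (!is.null(raw$svm$gamma_grid)) list(gammaGrid = unlist(raw$svm$gamma_grid)),
      if (!is.null(raw$svm$n_folds)) list(nFolds = raw$svm$n_folds))),
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    outDir = if (is.null(raw$out_dir)) "." else resolve(raw$out_dir))
  stopifnot(cfg$featureMode %in% c("signal", "kmer"))
  cfg
}
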