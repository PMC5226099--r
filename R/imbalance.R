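# Class-imbalance reduction. Enhancers are ~2% of genome windows; the
# negative class is cut to ratio:1 (default 10:1) by k-means-guided
# sub-sampling so the retained negatives keep the feature diversity of
# the full negative set rather than collapsing onto its densest region.

# k-means with `nStarts` seeded restarts, initial centers drawn from the
# unique rows (duplicate rows would make stats::kmeans reject the random
# initial centers); the restart with the lowest total within-cluster sum
# of squares wins.
restartedKmeans <- function(x, k, nStarts, maxIter) {
  ux <- unique(x)
  k <- min(k, nrow(ux))
  if (k == 1L) {
    return(list(cluster = rep(1L, nrow(x))))
  }
  best <- NULL
  for (i in seq_len(nStarts)) {
    centers <- ux[sample(nrow(ux), k), , drop = FALSE]
    km <- tryCatch(
      kmeans(x, centers = centers, iter.max = maxIter),
      error = function(e) NULL,
      warning = function(w) suppressWarnings(
        kmeans(x, centers = centers, iter.max = maxIter,
               algorithm = "Lloyd")))
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss)) {
      best <- km
    }
  }
  if (is.null(best)) stop("k-means failed on the negative feature matrix")
  best
}

# Largest-remainder apportionment of `total` draws over cluster sizes,
# proportional to size; empty clusters get nothing and their share flows
# to the others automatically. Ties on the fractional part break toward
# the lower cluster index for determinism.
allocateQuota <- function(sizes, total) {
  stopifnot(total <= sum(sizes))
  exact <- total * sizes / sum(sizes)
  quota <- floor(exact)
  remainder <- total - sum(quota)
  if (remainder > 0) {
    frac <- exact - quota
    topUp <- order(-frac, seq_along(sizes))[seq_len(remainder)]
    quota[topUp] <- quota[topUp] + 1L
  }
  as.integer(quota)
}

#' Sub-sample negatives to a fixed class ratio
#'
#' Keeps every positive window and draws `min(ratio * n_pos, n_neg)`
#' negatives without replacement. Negatives are first k-means-clustered
#' on their min-max-normalized feature vectors; the draw is then
#' allocated to clusters proportionally to cluster size
#' (largest-remainder rounding) and taken uniformly at random within each
#' cluster, so the retained negatives span the negative class's feature
#' space instead of oversampling its bulk. Output order is positives
#' first, then sampled negatives; the result is deterministic given
#' `config$seed`.
#'
#' @param dataset an [EnhancerDataset] with at least one positive window.
#' @param config a [samplingConfig()].
#' @return The sub-sampled [EnhancerDataset].
#' @examples
#' # 100 positives + 5000 negatives in, 100 + 1000 out at the default 1:10
#' @export
subsampleNegatives <- function(dataset, config = samplingConfig()) {
  stopifnot(is(dataset, "EnhancerDataset"), inherits(config, "sampling_config"))
  labels <- windowLabels(dataset)
  posIdx <- which(labels == 1L)
  negIdx <- which(labels == 0L)
  if (!length(posIdx)) {
    stop("dataset has no positive windows; nothing to balance against")
  }
  target <- min(floor(config$ratio * length(posIdx)), length(negIdx))
  if (target >= length(negIdx)) {
    keep <- c(posIdx, negIdx)
    return(dataset[keep, ])
  }
  feats <- minmaxApply(featureMatrix(dataset), minmaxFit(featureMatrix(dataset)))
  sampled <- withSeed(config$seed, {
    km <- restartedKmeans(feats[negIdx, , drop = FALSE],
                          k = min(config$nClusters, length(negIdx)),
                          nStarts = config$nStarts, maxIter = config$maxIter)
    clusters <- km$cluster
    sizes <- tabulate(clusters, nbins = max(clusters))
    quota <- allocateQuota(sizes, target)
    unlist(lapply(seq_along(quota), function(c) {
      members <- negIdx[clusters == c]
      if (quota[c] == 0L) return(integer())
      if (quota[c] == length(members)) return(members)
      sample(members, quota[c])
    }), use.names = FALSE)
  })
  dataset[c(posIdx, sort(sampled)), ]
}
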