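# Fixtures are built in code at test time; nothing is read from disk
# except files the tests themselves write to tempdir().

# A dataset whose first feature separates the classes perfectly.
makeSeparableDataset <- function(nPos = 40, nNeg = 160, seed = 1,
                                 tissue = "sep") {
  set.seed(seed)
  n <- nPos + nNeg
  labels <- rep(c(1L, 0L), c(nPos, nNeg))
  feats <- cbind(
    sig = ifelse(labels == 1L, runif(n, 5, 9), runif(n, 0, 2)),
    noise1 = runif(n), noise2 = runif(n))
  enhancerDataset(feats, labels, dummyWindows(n), tissue = tissue)
}

# Pure-noise features with labels drawn independently of them.
makeNoiseDataset <- function(n = 500, prevalence = 0.5, seed = 1,
                             tissue = "noise") {
  set.seed(seed)
  labels <- as.integer(runif(n) < prevalence)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
  feats <- cbind(a = runif(n), b = runif(n), c = runif(n))
  enhancerDataset(feats, labels, dummyWindows(n), tissue = tissue)
}

# Windows for in-memory datasets that never touch real coordinates.
dummyWindows <- function(n, width = 200) {
  GenomicRanges::GRanges("chrS",
    IRanges::IRanges(start = seq_len(n) * width - width + 1,
                     width = width))
}

# Strong-signal multi-tissue fixture: enhancer marks strongly enriched in
# every tissue (the signal-recovery regime).
strongSpec <- function(seed, nTissues = 4) {
  synthSpec(chromSizes = c(chr1 = 3e5, chr2 = 2e5), nTissues = nTissues,
            seed = seed)
}

# Complementary-marks fixture: tissues 1..k each have a different single
# informative mark; tissues k+1..2k are fresh draws with the same
# structure and serve as the pooled test set.
complementarySpec <- function(seed, k = 3, effect = 6) {
  marks <- data.frame(name = paste0("mark", seq_len(k)),
                      effect = rep(0, k), noise = rep(0.4, k))
  synthSpec(chromSizes = c(chr1 = 3e5, chr2 = 2e5), nTissues = 2L * k,
            marks = marks,
            effects = rbind(diag(k) * effect, diag(k) * effect),
            backgroundRate = 0.1, peakWidthRange = c(200, 500),
            seed = seed)
}

# Null fixture: zero enrichment everywhere.
nullSpec <- function(seed, nTissues = 3) {
  synthSpec(chromSizes = c(chr1 = 2e5), nTissues = nTissues,
            marks = data.frame(name = c("mA", "mB"), effect = c(0, 0),
                               noise = c(0.5, 0.5)),
            enhancerFraction = 0.04, seed = seed)
}

# Reduced grid used throughout the tests (the full default grid is a
# production setting, not a test problem size).
testSvmConfig <- function(nFolds = 10) {
  svmConfig(cGrid = c(2, 8, 32), gammaGrid = c(2, 8, 32), nFolds = nFolds)
}
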