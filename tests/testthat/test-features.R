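# Feature engineering: signal mapping, normalization, labeling, k-mers.

test_that("mapSignal spreads a peak over the windows it touches", {
  g <- makeWindows(c(chrA = 1000), width = 200)
  peak <- GRanges("chrA", IRanges(101, 300))  # 0-based 100-300
  peak$signalValue <- 5
  m <- mapSignal(list(mark = peak), g)
  expect_equal(unname(m[, "mark"]), c(5, 5, 0, 0, 0))
  # no peaks at all -> all-zero matrix
  m0 <- mapSignal(list(mark = GRanges()), g)
  expect_true(all(m0 == 0))
})

test_that("mapSignal equals the all-pairs overlap oracle on random peaks", {
  set.seed(21)
  g <- makeWindows(c(chrA = 4000, chrB = 2200), width = 200)
  win <- binWindows(g)
  makePeaks <- function(n) {
    s <- sample(0:3800, n)
    gr <- GRanges(sample(c("chrA", "chrB"), n, TRUE),
                  IRanges(s + 1L, s + sample(50:700, n)))
    gr$signalValue <- round(runif(n, 0.5, 20), 3)
    gr
  }
  peaks <- list(m1 = makePeaks(30), m2 = makePeaks(30))
  got <- mapSignal(peaks, g)
  # O(n*m) brute force: scan every peak for every (window, mark)
  oracle <- matrix(0, length(win), 2, dimnames = list(NULL, c("m1", "m2")))
  for (mi in 1:2) {
    p <- peaks[[mi]]
    for (wi in seq_along(win)) {
      best <- 0
      for (pi in seq_along(p)) {
        sameChrom <- as.character(seqnames(win)[wi]) ==
          as.character(seqnames(p)[pi])
        if (sameChrom &&
            start(p)[pi] <= end(win)[wi] && end(p)[pi] >= start(win)[wi]) {
          best <- max(best, p$signalValue[pi])
        }
      }
      oracle[wi, mi] <- best
    }
  }
  expect_equal(got, oracle)
  # count aggregation mode agrees with a brute-force overlap count
  gotCount <- mapSignal(peaks["m1"], g, aggregate = "count")
  oracleCount <- vapply(seq_along(win), function(wi) {
    p <- peaks$m1
    sum(as.character(seqnames(p)) == as.character(seqnames(win)[wi]) &
          start(p) <= end(win)[wi] & end(p) >= start(win)[wi])
  }, numeric(1))
  expect_equal(unname(gotCount[, 1]), oracleCount)
})

test_that("peaks on chromosomes outside the grid are ignored with a warning", {
  g <- makeWindows(c(chrA = 1000), width = 200)
  peak <- GRanges(c("chrA", "chrZ"), IRanges(c(1, 1), c(100, 100)))
  peak$signalValue <- c(2, 9)
  expect_warning(m <- mapSignal(list(mark = peak), g), "chrZ|absent")
  expect_equal(max(m), 2)
})

test_that("min-max normalization follows the formula and its edge cases", {
  expect_equal(unname(minmaxNormalize(cbind(x = c(2, 4, 6)))[, 1]),
               c(0, 0.5, 1))
  # idempotent on an already-normalized column
  m <- cbind(x = c(0, 0.25, 1))
  expect_equal(minmaxNormalize(m), m)
  # constant column degenerates to zeros, with a warning
  expect_warning(z <- minmaxNormalize(cbind(k = c(5, 5, 5))), "constant")
  expect_equal(unname(z[, 1]), c(0, 0, 0))
  # range is always inside [0,1]
  set.seed(2)
  r <- minmaxNormalize(matrix(rnorm(200), ncol = 4))
  expect_true(min(r) >= 0 && max(r) <= 1)
})

test_that("a train-fitted normalization clips out-of-range test values", {
  train <- cbind(s = c(0, 10))
  fit <- minmaxFit(train)
  test <- cbind(s = c(-5, 5, 20))
  expect_equal(unname(minmaxApply(test, fit, clip = TRUE)[, 1]), c(0, 0.5, 1))
})

test_that("window labeling follows the fractional-overlap rule", {
  g <- makeWindows(c(chrA = 2000), width = 200)
  # full containment: 0-600 covers windows 1..3 completely
  lab <- labelWindows(g, GRanges("chrA", IRanges(1, 600)))
  expect_equal(lab, c(1L, 1L, 1L, rep(0L, 7)))
  # 0-based 150-210: 50 bp in window 1 and 10 bp in window 2, both < 100
  lab2 <- labelWindows(g, GRanges("chrA", IRanges(151, 210)))
  expect_equal(sum(lab2), 0L)
  # exactly half the window (100 bp) qualifies under >= 50%
  lab3 <- labelWindows(g, GRanges("chrA", IRanges(101, 200)))
  expect_equal(lab3[1], 1L)
  # nothing labeled without intervals
  expect_equal(sum(labelWindows(g, GRanges())), 0L)
  # the threshold is configurable
  lab4 <- labelWindows(g, GRanges("chrA", IRanges(151, 210)), minOverlap = 0.2)
  expect_equal(lab4[1], 1L)
})

test_that("labeling agrees with a per-window overlap-length oracle", {
  set.seed(31)
  g <- makeWindows(c(chrA = 6000), width = 200)
  win <- binWindows(g)
  s <- sample(0:5800, 25)
  labs <- GRanges("chrA", IRanges(s + 1L, s + sample(20:500, 25)))
  got <- labelWindows(g, labs)
  oracle <- vapply(seq_along(win), function(wi) {
    best <- 0L
    for (li in seq_along(labs)) {
      ov <- min(end(win)[wi], end(labs)[li]) -
        max(start(win)[wi], start(labs)[li]) + 1L
      best <- max(best, ov)
    }
    as.integer(best >= 0.5 * width(win)[wi])
  }, integer(1))
  expect_equal(got, oracle)
})

test_that("k-mer frequencies count sliding windows correctly", {
  f1 <- kmerFrequencies("AAAA", kSet = 1)
  expect_equal(unname(f1["A"]), 1)
  expect_equal(sum(f1), 1)
  f2 <- kmerFrequencies("ACGT", kSet = 2)
  expect_equal(unname(f2[c("AC", "CG", "GT")]), rep(1 / 3, 3))
  expect_equal(sum(f2 > 0), 3)
  # full default set is 4 + 16 + 64 + 256 features
  expect_length(kmerFrequencies("ACGTACGT"), 340)
})

test_that("k-mer blocks sum to 1 and match a sliding-window oracle", {
  set.seed(41)
  seqc <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  got <- kmerFrequencies(seqc, kSet = 1:4)
  chars <- strsplit(seqc, "")[[1]]
  for (k in 1:4) {
    block <- got[nchar(names(got)) == k]
    expect_equal(sum(block), 1, tolerance = 1e-12)
    # naive oracle: enumerate all length-k windows and tabulate
    kmers <- vapply(1:(500 - k + 1), function(i) {
      paste(chars[i:(i + k - 1)], collapse = "")
    }, character(1))
    tab <- table(kmers) / length(kmers)
    expect_equal(unname(block[names(tab)]), unname(as.numeric(tab)))
    expect_equal(sum(block[setdiff(names(block), names(tab))]), 0)
  }
})

test_that("N-containing windows are excluded from count and denominator", {
  # ACGNA, k=2: windows AC CG GN NA -> only AC and CG are valid
  f <- kmerFrequencies("ACGNA", kSet = 2)
  expect_equal(unname(f["AC"]), 0.5)
  expect_equal(unname(f["CG"]), 0.5)
  expect_equal(sum(f), 1)
  # shorter than k -> all-zero block, no error
  expect_equal(sum(kmerFrequencies("AC", kSet = 3)), 0)
})

test_that("the per-window k-mer matrix matches per-window kmerFrequencies", {
  set.seed(51)
  seqs <- Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")))
  g <- makeWindows(c(chr1 = 1000), width = 200)
  mat <- kmerFeatureMatrix(seqs, g, kSet = 1:2)
  expect_equal(dim(mat), c(5L, 20L))
  win <- binWindows(g)
  for (i in c(1, 3, 5)) {
    sub <- as.character(Biostrings::subseq(seqs[[1]], start(win)[i], end(win)[i]))
    expect_equal(mat[i, ], kmerFrequencies(sub, kSet = 1:2))
  }
  expect_error(kmerFeatureMatrix(seqs, makeWindows(c(chr2 = 100))), "missing")
})

test_that("buildDataset assembles features and labels coherently", {
  g <- makeWindows(c(chrA = 1000), width = 200)
  peak <- GRanges("chrA", IRanges(1, 400))
  peak$signalValue <- 3
  ds <- buildDataset(list(m1 = peak), GRanges("chrA", IRanges(1, 200)), g,
                     tissue = "t1")
  expect_s4_class(ds, "EnhancerDataset")
  expect_equal(tissueName(ds), "t1")
  expect_equal(windowLabels(ds), c(1L, 0L, 0L, 0L, 0L))
  expect_equal(unname(featureMatrix(ds)[, 1]), c(3, 3, 0, 0, 0))
  expect_equal(markNames(ds), "m1")
})
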