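# Interval I/O: broadPeak/BED parsing, the window grid, prediction output.

writeTmp <- function(lines, ext = ".bed") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("broadPeak lines map to records field by field", {
  f <- writeTmp("chr1\t100\t500\tp1\t0\t.\t7.5\t-1\t-1")
  gr <- readBroadPeak(f)
  expect_length(gr, 1)
  expect_equal(as.character(seqnames(gr)), "chr1")
  expect_equal(start(gr) - 1L, 100L)  # file is 0-based half-open
  expect_equal(end(gr), 500L)
  expect_equal(gr$signalValue, 7.5)
  expect_equal(gr$name, "p1")
  expect_equal(gr$pValue, -1)

  # 3-column BED flows through with defaulted signal
  f3 <- writeTmp("chr2\t0\t200")
  gr3 <- readBroadPeak(f3)
  expect_equal(gr3$signalValue, 1)
  expect_equal(start(gr3), 1L)

  expect_length(readBroadPeak(writeTmp(character())), 0)
})

test_that("a synthetic broadPeak file agrees with a line-by-line re-parse", {
  set.seed(7)
  n <- 50
  lines <- sprintf("chr%d\t%d\t%d\tp%d\t%d\t.\t%.3f\t-1\t-1",
                   sample(1:3, n, TRUE), s <- sample(0:10000, n),
                   s + sample(50:900, n), seq_len(n),
                   sample(0:1000, n), runif(n, 0, 20))
  gr <- readBroadPeak(writeTmp(lines))
  expect_length(gr, n)
  # independent oracle: re-split every line and sum the spans
  parts <- strsplit(lines, "\t", fixed = TRUE)
  oracleSpan <- sum(vapply(parts, function(p) {
    as.integer(p[3]) - as.integer(p[2])
  }, integer(1)))
  expect_identical(sum(width(gr)), oracleSpan)
  oracleSignal <- sum(vapply(parts, function(p) as.numeric(p[7]), numeric(1)))
  expect_equal(sum(gr$signalValue), oracleSignal)
})

test_that("malformed peak lines fail with the offending line number", {
  f <- writeTmp(c("chr1\t0\t200", "chr1\txx\t300"))
  expect_error(readBroadPeak(f), "line 2.*non-integer")
  f2 <- writeTmp(c("chr1\t0\t200", "chr1\t500\t400\tp\t0\t.\t1\t-1\t-1"))
  expect_error(readBroadPeak(f2), "line 2.*invalid interval")
  f3 <- writeTmp("chr1\t100")
  expect_error(readBed(f3), "line 1.*fewer than 3")
})

test_that("BED reading keeps order, skips headers, and sorts like an oracle", {
  expect_equal(start(readBed(writeTmp("chr2\t0\t200"))) - 1L, 0L)
  withHeader <- writeTmp(c("track name=labels", "# comment",
                           "browser position chr1",
                           "chr1\t10\t20", "chr1\t30\t40"))
  expect_length(readBed(withHeader), 2)

  set.seed(3)
  n <- 20
  chrom <- sample(c("chr1", "chr2", "chr10"), n, TRUE)
  s <- sample(0:5000, n)
  gr <- readBed(writeTmp(sprintf("%s\t%d\t%d", chrom, s, s + 100)))
  expect_length(gr, n)
  # file order preserved
  expect_equal(start(gr) - 1L, s)
  # sorting matches an independent lexicographic + numeric sort
  srt <- GenomeInfoDb::sortSeqlevels(gr)
  srt <- sort(srt, ignore.strand = TRUE)
  oracle <- order(factor(chrom, levels = c("chr1", "chr2", "chr10")), s)
  expect_equal(start(srt) - 1L, s[oracle])
})

test_that("makeWindows tiles chromosomes exactly, truncated tail included", {
  g <- makeWindows(c(chrA = 1000), width = 200)
  expect_equal(length(g), 5)
  first <- binWindows(g)[1]
  expect_equal(c(start(first) - 1L, end(first)), c(0L, 200L))

  g2 <- makeWindows(c(chrA = 1001), width = 200)
  expect_equal(length(g2), 6)
  last <- binWindows(g2)[6]
  expect_equal(c(start(last) - 1L, end(last)), c(1000L, 1001L))

  # brute-force enumeration oracle over two chromosomes
  g3 <- makeWindows(c(chrA = 10000, chrB = 4600), width = 200)
  oracle <- do.call(rbind, lapply(list(c("chrA", 10000), c("chrB", 4600)),
    function(cs) {
      len <- as.integer(cs[2])
      starts <- seq(0L, len - 1L, by = 200L)
      data.frame(chrom = cs[1], start = starts,
                 end = pmin(starts + 200L, len))
    }))
  expect_equal(length(g3), nrow(oracle))  # 73
  expect_equal(length(g3), 73)
  w <- binWindows(g3)
  expect_equal(as.character(seqnames(w)), oracle$chrom)
  expect_equal(start(w) - 1L, oracle$start)
  expect_equal(end(w), oracle$end)

  expect_error(makeWindows(c(chrA = 1000), width = 0), "positive")
  expect_error(makeWindows(c(chrA = -5)), "positive")
})

test_that("window tiling is a partition: every position in exactly one bin", {
  g <- makeWindows(c(c1 = 517, c2 = 123, c3 = 1400), width = 100)
  w <- binWindows(g)
  for (chrom in names(chromSizes(g))) {
    len <- chromSizes(g)[[chrom]]
    cov <- integer(len)
    sub <- w[as.character(seqnames(w)) == chrom]
    for (i in seq_along(sub)) {
      idx <- start(sub)[i]:end(sub)[i]
      cov[idx] <- cov[idx] + 1L
    }
    expect_true(all(cov == 1L))
  }
})

test_that("prediction BED round-trips intervals and scales scores", {
  g <- makeWindows(c(chrA = 1000), width = 200)
  w <- binWindows(g)[1]
  f <- tempfile(fileext = ".bed")
  writePredictionsBed(w, 1.0, 1L, f)
  expect_equal(readBed(f)$score, 1000)

  writePredictionsBed(GRanges(), numeric(), integer(), f)
  expect_length(readBed(f), 0)

  set.seed(5)
  g2 <- makeWindows(c(chrA = 50000), width = 200)
  idx <- sample(length(g2), 100)
  win <- binWindows(g2)[idx]
  scores <- runif(100)
  back <- readBed(writePredictionsBed(win, scores, rbinom(100, 1, 0.3), f))
  expect_equal(as.character(seqnames(back)), as.character(seqnames(win)))
  expect_equal(start(back), start(win))
  expect_equal(end(back), end(win))
  expect_equal(back$score, round(scores * 1000))
})

test_that("peak records survive a write/read round-trip unchanged", {
  set.seed(11)
  n <- 30
  s <- sample(0:5000, n)
  gr <- GRanges(sample(c("chr1", "chr2"), n, TRUE), IRanges(s + 1L, s + 300L))
  mcols(gr) <- S4Vectors::DataFrame(
    name = paste0("p", seq_len(n)), score = sample(0:1000, n),
    signalValue = round(runif(n, 0, 50), 3),
    pValue = rep(-1, n), qValue = rep(-1, n))
  f <- tempfile(fileext = ".broadPeak")
  back <- readBroadPeak(writeBroadPeak(gr, f))
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(back$signalValue, gr$signalValue)
  expect_equal(back$name, gr$name)
  expect_equal(back$score, gr$score)
})

test_that("chrom.sizes files round-trip", {
  f <- tempfile()
  sizes <- c(chr1 = 123456L, chr2 = 999L)
  expect_identical(readChromSizes(writeChromSizes(sizes, f)), sizes)
})
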