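# Synthetic multi-tissue epigenomes: valid broadPeak/BED/FASTA fixtures
# with the statistical structure the classifier assumes (a small fraction
# of windows positive, enhancer-associated marks enriched at positives,
# tissue-to-tissue variation), so the whole pipeline is testable without
# external downloads.

#' Specification of a synthetic multi-tissue epigenome
#'
#' The generative model: a fixed fraction of 200-bp windows are
#' enhancers, drawn from a pool shared across tissues plus
#' tissue-specific pools. Each histone mark emits background peaks at
#' random windows at rate `backgroundRate` with lognormal(meanlog =
#' `baseMeanlog`, sd = noise) signal. A mark with enrichment effect e > 0
#' additionally peaks over that tissue's enhancer windows: the emission
#' probability there is `1 - (1 - backgroundRate) * exp(-e)` and the
#' signal meanlog is `baseMeanlog + log1p(e)`. At e = 0 positives are
#' exactly exchangeable with background, which makes the null regime
#' (AUC ~ 0.5) reachable by construction.
#'
#' @param chromSizes named chromosome lengths (bp).
#' @param binWidth window width (bp).
#' @param enhancerFraction fraction of windows positive per tissue
#'   (default 0.02, the genome-wide enhancer prior).
#' @param nTissues number of tissues to emit.
#' @param sharedEnhancerFraction fraction of each tissue's enhancers
#'   drawn from the shared pool (tissue specificity dial).
#' @param marks data.frame with columns `name`, `effect` (>= 0) and
#'   `noise` (lognormal sdlog); `effect` may instead be supplied per
#'   tissue via `effects`.
#' @param effects optional nTissues x nMarks matrix overriding
#'   `marks$effect` per tissue (complementary-marks designs).
#' @param backgroundRate background peak emission probability per window.
#' @param baseMeanlog background signal meanlog.
#' @param peakWidthRange range of emitted peak widths (bp).
#' @param motif tetranucleotide enriched in enhancer windows by
#'   [simulateSequences()].
#' @param seed integer seed; everything downstream is deterministic in it.
#' @return A `synth_spec` list.
#' @export
synthSpec <- function(chromSizes = c(chr1 = 6e5, chr2 = 4e5),
                      binWidth = 200,
                      enhancerFraction = 0.02,
                      nTissues = 4,
                      sharedEnhancerFraction = 0.5,
                      marks = data.frame(
                        name = c("H3K4me1", "H3K27ac", "H3K4me3", "H3K9me3"),
                        effect = c(3, 3, 1.5, 0),
                        noise = c(0.5, 0.5, 0.5, 0.5)),
                      effects = NULL,
                      backgroundRate = 0.15,
                      baseMeanlog = 0,
                      peakWidthRange = c(200, 1000),
                      motif = "GGAA",
                      seed = 1L) {
  stopifnot(enhancerFraction > 0, enhancerFraction < 1,
            nTissues >= 1, sharedEnhancerFraction >= 0,
            sharedEnhancerFraction <= 1,
            all(marks$effect >= 0), all(marks$noise > 0),
            backgroundRate > 0, backgroundRate < 1,
            length(peakWidthRange) == 2, peakWidthRange[1] >= 1,
            nchar(motif) == 4)
  if (!is.null(effects)) {
    effects <- as.matrix(effects)
    stopifnot(nrow(effects) == nTissues, ncol(effects) == nrow(marks),
              all(effects >= 0))
    colnames(effects) <- marks$name
  }
  spec <- list(chromSizes = chromSizes, binWidth = as.integer(binWidth),
               enhancerFraction = enhancerFraction,
               nTissues = as.integer(nTissues),
               sharedEnhancerFraction = sharedEnhancerFraction,
               marks = marks, effects = effects,
               backgroundRate = backgroundRate, baseMeanlog = baseMeanlog,
               peakWidthRange = as.integer(peakWidthRange),
               motif = toupper(motif), seed = seed)
  class(spec) <- "synth_spec"
  spec
}

markEffect <- function(spec, tissueIndex, markIndex) {
  if (!is.null(spec$effects)) {
    spec$effects[tissueIndex, markIndex]
  } else {
    spec$marks$effect[markIndex]
  }
}

#' Draw the ground-truth enhancer windows for all tissues
#'
#' Each tissue's positives are the shared pool (common to all tissues)
#' plus a tissue-specific pool; tissue-specific pools are disjoint from
#' the shared pool and from each other. The per-tissue positive count is
#' exactly `round(enhancerFraction * n_windows)`.
#'
#' @param spec a [synthSpec()].
#' @return List with `grid` (a [WindowGrid]) and `truth`, an
#'   n_windows x nTissues 0/1 matrix with columns `tissue1..tissueN`.
#' @export
simulateTruth <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  grid <- makeWindows(spec$chromSizes, width = spec$binWidth)
  n <- length(grid)
  nPos <- round(spec$enhancerFraction * n)
  if (nPos < 1) stop("enhancerFraction too small: no positive windows")
  nShared <- round(spec$sharedEnhancerFraction * nPos)
  nSpecific <- nPos - nShared
  if (nShared + spec$nTissues * nSpecific > n) {
    stop("enhancerFraction too high: shared and tissue-specific enhancer ",
         "pools cannot be disjoint")
  }
  truth <- withSeed(spec$seed, {
    shared <- sample(n, nShared)
    remaining <- setdiff(seq_len(n), shared)
    m <- matrix(0L, nrow = n, ncol = spec$nTissues,
                dimnames = list(NULL, paste0("tissue", seq_len(spec$nTissues))))
    for (t in seq_len(spec$nTissues)) {
      specific <- if (nSpecific > 0) sample(remaining, nSpecific) else integer()
      remaining <- setdiff(remaining, specific)
      m[c(shared, specific), t] <- 1L
    }
    m
  })
  list(grid = grid, truth = truth)
}

clampPeak <- function(center, halfWidth, chromLen) {
  s <- pmax(1L, as.integer(center - halfWidth))
  e <- pmin(chromLen, as.integer(center + halfWidth))
  list(start = s, end = pmax(e, s))
}

emptyPeaks <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(name = character(), score = integer(),
                         signalValue = numeric(), pValue = numeric(),
                         qValue = numeric())
  gr
}

emitPeaks <- function(windows, chromLens, prob, meanlog, sdlog, widthRange,
                      exactFootprint = FALSE) {
  hit <- which(runif(length(windows)) < prob)
  if (!length(hit)) return(emptyPeaks())
  w <- windows[hit]
  if (exactFootprint) {
    co <- list(start = start(w), end = end(w))
  } else {
    widths <- round(runif(length(hit), widthRange[1], widthRange[2]))
    centers <- (start(w) + end(w)) %/% 2L
    lens <- chromLens[as.character(seqnames(w))]
    co <- clampPeak(centers, widths %/% 2L, lens)
  }
  signal <- rlnorm(length(hit), meanlog = meanlog, sdlog = sdlog)
  gr <- GRanges(seqnames(w), IRanges(co$start, co$end))
  mcols(gr) <- DataFrame(name = paste0("peak", seq_along(gr)),
                         score = pmin(1000L, as.integer(round(signal * 100))),
                         signalValue = signal,
                         pValue = rep(-1, length(gr)),
                         qValue = rep(-1, length(gr)))
  sort(gr, ignore.strand = TRUE)
}

#' Generate one synthetic tissue's peak and label tracks
#'
#' Emits, per mark, a `GRanges` of broadPeak-style peaks (background
#' peaks everywhere at `backgroundRate`, enriched peaks over the tissue's
#' enhancer windows according to the mark's effect) plus the enhancer
#' label intervals (merged positive windows). Deterministic given the
#' spec seed and tissue index.
#'
#' @param spec a [synthSpec()].
#' @param truth result of [simulateTruth()] on the same spec.
#' @param tissueIndex tissue number in `1:nTissues`.
#' @return List with `peaks` (named list of `GRanges` per mark), `labels`
#'   (`GRanges`), and `labelVector` (0/1 per window).
#' @export
simulateTissue <- function(spec, truth, tissueIndex) {
  stopifnot(inherits(spec, "synth_spec"),
            tissueIndex >= 1, tissueIndex <= spec$nTissues)
  grid <- truth$grid
  win <- binWindows(grid)
  labels <- truth$truth[, tissueIndex]
  posWin <- win[labels == 1L]
  negWin <- win[labels == 0L]
  chromLens <- chromSizes(grid)
  peaks <- withSeed(spec$seed + 1000L * tissueIndex, {
    out <- list()
    for (m in seq_len(nrow(spec$marks))) {
      e <- markEffect(spec, tissueIndex, m)
      noise <- spec$marks$noise[m]
      bg <- emitPeaks(negWin, chromLens, prob = spec$backgroundRate,
                      meanlog = spec$baseMeanlog, sdlog = noise,
                      widthRange = spec$peakWidthRange)
      pPos <- 1 - (1 - spec$backgroundRate) * exp(-e)
      # enriched peaks coincide with the enhancer window footprint: the
      # emulated upstream data is already binned at window resolution, so
      # enrichment must not bleed onto windows the truth table calls negative
      en <- emitPeaks(posWin, chromLens, prob = pPos,
                      meanlog = spec$baseMeanlog + log1p(e), sdlog = noise,
                      widthRange = spec$peakWidthRange,
                      exactFootprint = e > 0)
      out[[spec$marks$name[m]]] <- sort(c(bg, en), ignore.strand = TRUE)
    }
    out
  })
  list(peaks = peaks,
       labels = reduce(posWin, ignore.strand = TRUE),
       labelVector = labels)
}

#' Generate genome sequence with motif-enriched enhancers
#'
#' Produces uniform random ACGT background of exactly the configured
#' chromosome lengths, then plants the spec's tetranucleotide motif at
#' several positions inside every window that is an enhancer in any
#' tissue, so k-mer features are informative about the labels.
#'
#' @param spec a [synthSpec()].
#' @param truth result of [simulateTruth()].
#' @param insertsPerWindow motif copies planted per enhancer window.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
simulateSequences <- function(spec, truth, insertsPerWindow = 5L) {
  stopifnot(inherits(spec, "synth_spec"))
  win <- binWindows(truth$grid)
  anyPos <- rowSums(truth$truth) > 0
  motifChars <- strsplit(spec$motif, "")[[1]]
  withSeed(spec$seed + 77L, {
    seqs <- lapply(names(spec$chromSizes), function(chrom) {
      len <- spec$chromSizes[[chrom]]
      chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      idx <- which(anyPos & as.character(seqnames(win)) == chrom)
      for (i in idx) {
        s <- start(win)[i]
        e <- end(win)[i]
        if (e - s + 1L < nchar(spec$motif)) next
        offsets <- sample(s:(e - nchar(spec$motif) + 1L),
                          min(insertsPerWindow, e - s), replace = FALSE)
        for (o in offsets) {
          chars[o:(o + nchar(spec$motif) - 1L)] <- motifChars
        }
      }
      paste(chars, collapse = "")
    })
    out <- DNAStringSet(unlist(seqs))
    names(out) <- names(spec$chromSizes)
    out
  })
}

#' Write a full synthetic experiment to disk
#'
#' Emits, under `outDir`: `chrom.sizes`, per-tissue per-mark broadPeak
#' files (`<tissue>_<mark>.broadPeak`), per-tissue enhancer label BEDs
#' (`<tissue>_labels.bed`), a long-format truth table `truth.tsv`
#' (window, tissue, label) and, optionally, `genome.fa`. Returns a
#' manifest usable directly by [trainEnhancerStack()]. Byte-identical
#' across runs with the same spec.
#'
#' @param spec a [synthSpec()].
#' @param outDir output directory (created if needed).
#' @param writeFasta also emit the motif-enriched genome FASTA.
#' @return List with `grid`, `truth`, `tissues` (per-tissue manifests of
#'   file paths), `chromSizesFile`, and `fastaFile` (or `NULL`).
#' @export
simulateExperiment <- function(spec, outDir, writeFasta = FALSE) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulateTruth(spec)
  win <- binWindows(truth$grid)
  chromSizesFile <- file.path(outDir, "chrom.sizes")
  writeChromSizes(spec$chromSizes, chromSizesFile)
  tissues <- vector("list", spec$nTissues)
  names(tissues) <- colnames(truth$truth)
  for (t in seq_len(spec$nTissues)) {
    tn <- names(tissues)[t]
    sim <- simulateTissue(spec, truth, t)
    markFiles <- setNames(
      file.path(outDir, sprintf("%s_%s.broadPeak", tn, names(sim$peaks))),
      names(sim$peaks))
    for (m in names(sim$peaks)) writeBroadPeak(sim$peaks[[m]], markFiles[[m]])
    labelFile <- file.path(outDir, sprintf("%s_labels.bed", tn))
    labTab <- data.frame(chrom = as.character(seqnames(sim$labels)),
                         start = start(sim$labels) - 1L,
                         end = end(sim$labels))
    write.table(labTab, labelFile, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    tissues[[t]] <- list(name = tn, marks = as.list(markFiles),
                         labels = labelFile)
  }
  truthLong <- do.call(rbind, lapply(seq_len(spec$nTissues), function(t) {
    data.frame(chrom = as.character(seqnames(win)),
               start = start(win) - 1L, end = end(win),
               tissue = colnames(truth$truth)[t],
               label = truth$truth[, t])
  }))
  write.table(truthLong, file.path(outDir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fastaFile <- NULL
  if (writeFasta) {
    fastaFile <- file.path(outDir, "genome.fa")
    writeXStringSet(simulateSequences(spec, truth), fastaFile)
  }
  list(grid = truth$grid, truth = truth$truth, tissues = tissues,
       chromSizesFile = chromSizesFile, fastaFile = fastaFile,
       truthFile = file.path(outDir, "truth.tsv"))
}

#' Build in-memory datasets for a synthetic experiment
#'
#' Convenience for tests and demos: generates every tissue with
#' [simulateTissue()] and assembles [EnhancerDataset] objects directly,
#' skipping the file round-trip.
#'
#' @param spec a [synthSpec()].
#' @return List with `grid`, `truth` and `datasets` (one
#'   [EnhancerDataset] per tissue).
#' @export
simulateDatasets <- function(spec) {
  truth <- simulateTruth(spec)
  datasets <- lapply(seq_len(spec$nTissues), function(t) {
    sim <- simulateTissue(spec, truth, t)
    feats <- mapSignal(sim$peaks, truth$grid)
    enhancerDataset(feats, sim$labelVector, binWindows(truth$grid),
                    tissue = colnames(truth$truth)[t])
  })
  names(datasets) <- colnames(truth$truth)
  list(grid = truth$grid, truth = truth$truth, datasets = datasets)
}
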