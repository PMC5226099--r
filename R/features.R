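# Feature engineering: peak signal -> per-window matrix, min-max
# normalization, window labeling, and the DNA k-mer feature mode.

#' Map peak signal onto a window grid
#'
#' Builds the raw (unnormalized) feature matrix: entry (w, m) is the
#' aggregated `signalValue` of all mark-m peaks overlapping window w by at
#' least 1 bp, and 0 where no peak overlaps. The default aggregation is
#' the maximum, which is scale-stable for enrichment statistics; `"sum"`,
#' `"mean"` and `"count"` are available (`"count"` gives peak counts per
#' window instead of signal).
#'
#' Peaks on chromosomes absent from the grid are ignored with a warning.
#'
#' @param peakSets named list of `GRanges` (one per mark) as returned by
#'   [readBroadPeak()].
#' @param grid a [WindowGrid].
#' @param aggregate how to combine multiple peaks in one window.
#' @return Numeric matrix, windows x marks.
#' @export
mapSignal <- function(peakSets, grid,
                      aggregate = c("max", "sum", "mean", "count")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is(grid, "WindowGrid"), is.list(peakSets))
  if (is.null(names(peakSets)) || any(!nzchar(names(peakSets)))) {
    stop("peakSets must be a named list (one entry per mark)")
  }
  win <- binWindows(grid)
  mat <- matrix(0, nrow = length(win), ncol = length(peakSets),
                dimnames = list(NULL, names(peakSets)))
  aggFun <- switch(aggregate, max = max, sum = sum, mean = mean,
                   count = length)
  for (m in names(peakSets)) {
    peaks <- peakSets[[m]]
    if (!length(peaks)) next
    onGrid <- as.character(seqnames(peaks)) %in% seqlevels(win)
    if (!all(onGrid)) {
      warning(sprintf("mark %s: ignoring %d peak(s) on chromosomes absent from the grid",
                      m, sum(!onGrid)))
      peaks <- peaks[onGrid]
      if (!length(peaks)) next
    }
    peaks <- keepSeqlevels(peaks, seqlevels(win), pruning.mode = "coarse")
    hits <- findOverlaps(win, peaks, minoverlap = 1L, ignore.strand = TRUE)
    if (!length(hits)) next
    sig <- mcols(peaks)$signalValue
    if (is.null(sig)) sig <- rep(1, length(peaks))
    agg <- tapply(sig[subjectHits(hits)], queryHits(hits), aggFun)
    mat[as.integer(names(agg)), m] <- as.numeric(agg)
  }
  mat
}

#' Fit per-column min-max normalization parameters
#'
#' @param m numeric matrix.
#' @return List with `min` and `max` per column, for [minmaxApply()].
#' @seealso [minmaxNormalize()]
#' @export
minmaxFit <- function(m) {
  m <- as.matrix(m)
  if (!length(m)) stop("cannot fit normalization on an empty matrix")
  list(min = apply(m, 2, min), max = apply(m, 2, max))
}

#' Apply a fitted min-max normalization
#'
#' Maps each column x to (x - min) / (max - min) with the `min`/`max`
#' fitted by [minmaxFit()]. Columns that were constant at fit time
#' (max = min) map to all zeros: a constant feature is uninformative
#' either way, and zeroing keeps the pipeline total. With `clip = TRUE`
#' (the right choice when applying a training-set fit to new data) the
#' result is clamped into \[0,1\].
#'
#' @param m numeric matrix with the same columns the fit was made on.
#' @param fit result of [minmaxFit()].
#' @param clip clamp output into \[0,1\].
#' @return Normalized matrix of the same shape.
#' @export
minmaxApply <- function(m, fit, clip = FALSE) {
  m <- as.matrix(m)
  stopifnot(ncol(m) == length(fit$min))
  rng <- fit$max - fit$min
  constant <- rng <= 0
  rng[constant] <- 1
  out <- sweep(sweep(m, 2, fit$min, "-"), 2, rng, "/")
  out[, constant] <- 0
  if (clip) {
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  out
}

#' Min-max normalize a feature matrix to \[0,1\]
#'
#' Convenience wrapper: fits [minmaxFit()] on `m` itself and applies it,
#' so every non-constant column spans exactly \[0,1\]. Constant columns
#' are zeroed with a warning. Idempotent on already-normalized columns.
#'
#' @param m numeric matrix.
#' @return Normalized matrix.
#' @examples
#' minmaxNormalize(cbind(a = c(2, 4, 6)))  # 0, 0.5, 1
#' @export
minmaxNormalize <- function(m) {
  fit <- minmaxFit(m)
  constant <- fit$max - fit$min <= 0
  if (any(constant)) {
    warning("constant feature column(s) mapped to zero: ",
            paste(colnames(as.matrix(m))[constant], collapse = ", "))
  }
  minmaxApply(m, fit, clip = FALSE)
}

#' Label windows by overlap with enhancer intervals
#'
#' A window is labeled 1 when at least `minOverlap` of its own width is
#' covered by a single label interval (EP300 peak or CAGE enhancer call),
#' 0 otherwise. The default 0.5 avoids labeling windows touched by a
#' single bp while not requiring full containment; truncated end-of-
#' chromosome windows are judged against their own (shorter) width.
#'
#' @param grid a [WindowGrid].
#' @param labelIntervals `GRanges` of label intervals.
#' @param minOverlap minimum fraction of the window covered by one
#'   interval, in (0, 1].
#' @return Integer 0/1 vector, one per window.
#' @export
labelWindows <- function(grid, labelIntervals, minOverlap = 0.5) {
  stopifnot(is(grid, "WindowGrid"), minOverlap > 0, minOverlap <= 1)
  win <- binWindows(grid)
  labels <- integer(length(win))
  if (!length(labelIntervals)) return(labels)
  keep <- as.character(seqnames(labelIntervals)) %in% seqlevels(win)
  labelIntervals <- labelIntervals[keep]
  if (!length(labelIntervals)) return(labels)
  labelIntervals <- keepSeqlevels(labelIntervals, seqlevels(win),
                                  pruning.mode = "coarse")
  hits <- findOverlaps(win, labelIntervals, ignore.strand = TRUE)
  if (!length(hits)) return(labels)
  ovWidth <- width(pintersect(win[queryHits(hits)],
                              labelIntervals[subjectHits(hits)],
                              ignore.strand = TRUE))
  need <- minOverlap * width(win[queryHits(hits)])
  hit <- unique(queryHits(hits)[ovWidth >= need])
  labels[hit] <- 1L
  labels
}

#' k-mer frequency vector of a DNA sequence
#'
#' For each k in `kSet`, counts every k-mer over \{A,C,G,T\} in sliding
#' windows and divides by the number of valid k-length windows; windows
#' containing N (or any non-ACGT letter) are skipped and excluded from
#' the denominator, so each k-block sums to 1 on N-free sequence. Blocks
#' are concatenated in lexicographic k-mer order; the default
#' `kSet = 1:4` (single base, di-, tri- and tetra-nucleotide) yields
#' 4 + 16 + 64 + 256 = 340 features. A sequence shorter than k gives an
#' all-zero block for that k.
#'
#' @param sequence DNA as a character string or [Biostrings::DNAString].
#' @param kSet integer k values.
#' @return Named numeric frequency vector.
#' @examples
#' kmerFrequencies("ACGT", kSet = 2)[c("AC", "CG", "GT")]  # each 1/3
#' @export
kmerFrequencies <- function(sequence, kSet = 1:4) {
  stopifnot(all(kSet >= 1))
  if (is.character(sequence)) sequence <- DNAString(sequence)
  out <- lapply(sort(unique(as.integer(kSet))), function(k) {
    nmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    if (length(sequence) < k) {
      return(setNames(numeric(length(nmers)), nmers))
    }
    counts <- oligonucleotideFrequency(sequence, width = k)
    denom <- sum(counts)
    if (denom == 0) counts[] <- 0 else counts <- counts / denom
    counts
  })
  unlist(out)
}

#' Per-window k-mer feature matrix from genome sequence
#'
#' Extracts each window's sequence and computes [kmerFrequencies()] for
#' all windows at once. This is the DNA-sequence feature mode: features
#' shared across tissues, labels still per tissue.
#'
#' @param seqs [Biostrings::DNAStringSet] named by chromosome (or a FASTA
#'   path).
#' @param grid a [WindowGrid]; chromosomes must be present in `seqs` and
#'   at least as long as the grid says.
#' @param kSet integer k values (default 1:4, 340 features).
#' @return Numeric matrix, windows x k-mers.
#' @export
kmerFeatureMatrix <- function(seqs, grid, kSet = 1:4) {
  if (is.character(seqs) && length(seqs) == 1L) {
    seqs <- readDNAStringSet(seqs)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  }
  stopifnot(is(grid, "WindowGrid"))
  sizes <- chromSizes(grid)
  missing <- setdiff(names(sizes), names(seqs))
  if (length(missing)) {
    stop("sequences missing for chromosome(s): ", paste(missing, collapse = ", "))
  }
  win <- binWindows(grid)
  kSet <- sort(unique(as.integer(kSet)))
  blocks <- vector("list", length(kSet))
  for (ki in seq_along(kSet)) {
    k <- kSet[ki]
    mat <- matrix(0, nrow = length(win),
                  ncol = 4^k,
                  dimnames = list(NULL,
                                  Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)))
    for (chrom in names(sizes)) {
      idx <- which(as.character(seqnames(win)) == chrom)
      if (!length(idx)) next
      v <- Views(seqs[[chrom]], start = start(win)[idx], end = end(win)[idx])
      counts <- oligonucleotideFrequency(v, width = k)
      denom <- rowSums(counts)
      denom[denom == 0] <- 1
      mat[idx, ] <- counts / denom
    }
    blocks[[ki]] <- mat
  }
  do.call(cbind, blocks)
}

#' Build a labeled per-window dataset from peak files
#'
#' Assembles one tissue's [EnhancerDataset]: maps each mark's peaks onto
#' the grid with [mapSignal()] (raw signal; normalization is fitted later
#' on training data only) and labels windows with [labelWindows()].
#'
#' @param peakSets named list of per-mark peak `GRanges` (or file paths,
#'   read with [readBroadPeak()]).
#' @param labelIntervals `GRanges` of enhancer label intervals, or a BED
#'   path.
#' @param grid a [WindowGrid].
#' @param tissue tissue / cell-line name.
#' @param aggregate passed to [mapSignal()].
#' @param minOverlap passed to [labelWindows()].
#' @return An [EnhancerDataset].
#' @export
buildDataset <- function(peakSets, labelIntervals, grid, tissue = "tissue",
                         aggregate = "max", minOverlap = 0.5) {
  peakSets <- lapply(peakSets, function(p) {
    if (is.character(p)) readBroadPeak(p) else p
  })
  if (is.character(labelIntervals)) labelIntervals <- readBed(labelIntervals)
  features <- mapSignal(peakSets, grid, aggregate = aggregate)
  labels <- labelWindows(grid, labelIntervals, minOverlap = minOverlap)
  enhancerDataset(features, labels, binWindows(grid), tissue = tissue)
}

#' Build a labeled k-mer dataset from genome sequence
#'
#' The DNA-sequence counterpart of [buildDataset()]: features are
#' per-window k-mer frequencies from [kmerFeatureMatrix()].
#'
#' @inheritParams buildDataset
#' @param seqs `DNAStringSet` or FASTA path.
#' @param kSet integer k values.
#' @return An [EnhancerDataset].
#' @export
buildKmerDataset <- function(seqs, labelIntervals, grid, tissue = "tissue",
                             kSet = 1:4, minOverlap = 0.5) {
  if (is.character(labelIntervals)) labelIntervals <- readBed(labelIntervals)
  features <- kmerFeatureMatrix(seqs, grid, kSet = kSet)
  labels <- labelWindows(grid, labelIntervals, minOverlap = minOverlap)
  enhancerDataset(features, labels, binWindows(grid), tissue = tissue)
}
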