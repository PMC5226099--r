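# Interval I/O. Everything on disk is BED-family (0-based half-open);
# in memory we use GRanges (1-based closed) and convert only at the file
# boundary. Strand is carried but ignored by the classifier: histone marks
# and enhancer calls are unstranded.

parseBedLines <- function(path, minCols) {
  lines <- readLines(path)
  lineNo <- seq_along(lines)
  keep <- nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  lineNo <- lineNo[keep]
  if (!length(lines)) {
    return(list(fields = list(), lineNo = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < minCols)) {
    bad <- lineNo[which(nf < minCols)[1]]
    stop(sprintf("%s: line %d has fewer than %d tab-separated columns",
                 path, bad, minCols))
  }
  list(fields = fields, lineNo = lineNo)
}

bedCoordinates <- function(fields, lineNo, path) {
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start0) | is.na(end))
  if (length(bad)) {
    stop(sprintf("%s: line %d has non-integer coordinates", path, lineNo[bad[1]]))
  }
  bad <- which(end <= start0 | start0 < 0 | !nzchar(chrom))
  if (length(bad)) {
    stop(sprintf("%s: line %d has an invalid interval (end <= start or start < 0)",
                 path, lineNo[bad[1]]))
  }
  list(chrom = chrom, start0 = start0, end = end)
}

bedColumn <- function(fields, i, default) {
  vapply(fields, function(f) if (length(f) >= i) f[[i]] else default,
         character(1))
}

#' Read an ENCODE broadPeak (or plain BED) peak file
#'
#' Parses a 9-column tab-separated ENCODE broadPeak file into a `GRanges`
#' with one range per line, in file order. Plain BED files with at least
#' 3 columns are accepted too: missing optional columns are defaulted
#' (`signalValue` = 1, so BED label files flow through the same reader).
#' File coordinates are 0-based half-open and round-trip unchanged.
#'
#' @param path path to a broadPeak / BED file.
#' @return A `GRanges` with metadata columns `name`, `score`,
#'   `signalValue`, `pValue`, `qValue`.
#' @examples
#' f <- tempfile(fileext = ".broadPeak")
#' writeLines("chr1\t100\t500\tp1\t0\t.\t7.5\t-1\t-1", f)
#' readBroadPeak(f)
#' @export
readBroadPeak <- function(path) {
  p <- parseBedLines(path, minCols = 3L)
  if (!length(p$fields)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(name = character(), score = integer(),
                           signalValue = numeric(), pValue = numeric(),
                           qValue = numeric())
    return(gr)
  }
  co <- bedCoordinates(p$fields, p$lineNo, path)
  signal <- suppressWarnings(as.numeric(bedColumn(p$fields, 7L, "1")))
  signal[is.na(signal)] <- 1
  if (any(signal < 0)) {
    stop(sprintf("%s: line %d has a negative signal value", path,
                 p$lineNo[which(signal < 0)[1]]))
  }
  score <- suppressWarnings(as.integer(bedColumn(p$fields, 5L, "0")))
  score[is.na(score)] <- 0L
  strand <- bedColumn(p$fields, 6L, "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(co$chrom, IRanges(co$start0 + 1L, co$end), strand = strand)
  mcols(gr) <- DataFrame(
    name = bedColumn(p$fields, 4L, "."),
    score = score,
    signalValue = signal,
    pValue = suppressWarnings(as.numeric(bedColumn(p$fields, 8L, "-1"))),
    qValue = suppressWarnings(as.numeric(bedColumn(p$fields, 9L, "-1"))))
  gr
}

#' Read a BED interval file
#'
#' Reads intervals from a >= 3-column BED file (track/browser/comment
#' lines skipped) into a `GRanges` in file order.
#'
#' @param path path to a BED file.
#' @return A `GRanges`; `name` and `score` columns are kept when present.
#' @export
readBed <- function(path) {
  p <- parseBedLines(path, minCols = 3L)
  if (!length(p$fields)) return(GRanges())
  co <- bedCoordinates(p$fields, p$lineNo, path)
  strand <- bedColumn(p$fields, 6L, "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(co$chrom, IRanges(co$start0 + 1L, co$end), strand = strand)
  score <- suppressWarnings(as.numeric(bedColumn(p$fields, 5L, "0")))
  score[is.na(score)] <- 0
  mcols(gr) <- DataFrame(name = bedColumn(p$fields, 4L, "."), score = score)
  gr
}

#' Read a chrom.sizes table
#'
#' @param path two-column (name TAB length) chromosome size file.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "size"),
                    colClasses = c("character", "integer"))
  if (any(tab$size <= 0L)) stop(path, ": chromosome lengths must be positive")
  setNames(tab$size, tab$chrom)
}

#' Tile a genome into fixed-width windows
#'
#' Partitions every chromosome from position 0 into consecutive bins of
#' `width` bp, keeping a truncated final bin where the chromosome length
#' is not a multiple of the width, so no position is dropped. The total
#' window count is `sum(ceiling(sizes / width))`.
#'
#' @param chromSizes named vector of chromosome lengths (bp), or a path to
#'   a chrom.sizes file.
#' @param width bin width in bp (default 200, the resolution the
#'   classifier works at).
#' @return A [WindowGrid].
#' @examples
#' makeWindows(c(chrA = 1001), width = 200)  # 6 windows, last truncated
#' @export
makeWindows <- function(chromSizes, width = 200) {
  if (is.character(chromSizes) && length(chromSizes) == 1L) {
    chromSizes <- readChromSizes(chromSizes)
  }
  width <- as.integer(width)
  if (is.na(width) || width <= 0L) stop("width must be a positive integer")
  sizes <- as.integer(chromSizes)
  names(sizes) <- names(chromSizes)
  if (is.null(names(sizes)) || anyNA(sizes) || any(sizes <= 0L)) {
    stop("chromSizes must be a named vector of positive lengths")
  }
  # direct construction (not tileGenome): a chromosome shorter than the
  # bin width must still yield its single truncated window
  startList <- lapply(sizes, function(len) seq.int(1L, len, by = width))
  starts <- unlist(startList, use.names = FALSE)
  lens <- rep(sizes, lengths(startList))
  tiles <- GRanges(rep(names(sizes), lengths(startList)),
                   IRanges(starts, pmin(starts + width - 1L, lens)),
                   seqlengths = sizes)
  new("WindowGrid", windows = tiles, chromSizes = sizes, binWidth = width)
}

#' Write window predictions as BED6
#'
#' Emits one BED6 line per window; the BED score column carries the
#' classifier confidence scaled to 0-1000 and the name column the
#' predicted class. Re-reading with [readBed()] recovers the intervals
#' exactly.
#'
#' @param windows `GRanges` (or [WindowGrid]) of the predicted windows.
#' @param scores numeric confidence/decision scores; values outside
#'   \[0,1\] are clamped for the BED score column only.
#' @param labels binary predicted labels.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePredictionsBed <- function(windows, scores, labels, path) {
  if (is(windows, "WindowGrid")) windows <- binWindows(windows)
  labels <- assertBinaryLabels(labels, "predicted labels")
  stopifnot(length(windows) == length(scores),
            length(windows) == length(labels))
  if (!length(windows)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  bedScore <- as.integer(round(pmin(1, pmax(0, scores)) * 1000))
  tab <- data.frame(chrom = as.character(seqnames(windows)),
                    start = start(windows) - 1L,
                    end = end(windows),
                    name = ifelse(labels == 1L, "enhancer", "background"),
                    score = bedScore,
                    strand = ".")
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a chrom.sizes table
#'
#' @param chromSizes named vector of chromosome lengths.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeChromSizes <- function(chromSizes, path) {
  write.table(data.frame(names(chromSizes), as.integer(chromSizes)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write peaks as ENCODE broadPeak
#'
#' @param peaks `GRanges` with `signalValue` (and optionally `name`,
#'   `score`, `pValue`, `qValue`) metadata columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBroadPeak <- function(peaks, path) {
  if (!length(peaks)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  m <- mcols(peaks)
  getCol <- function(nm, default) if (nm %in% colnames(m)) m[[nm]] else default
  n <- length(peaks)
  strand <- as.character(strand(peaks))
  strand[strand == "*"] <- "."
  tab <- data.frame(chrom = as.character(seqnames(peaks)),
                    start = start(peaks) - 1L,
                    end = end(peaks),
                    name = getCol("name", paste0("peak", seq_len(n))),
                    score = getCol("score", rep(0L, n)),
                    strand = strand,
                    signalValue = getCol("signalValue", rep(1, n)),
                    pValue = getCol("pValue", rep(-1, n)),
                    qValue = getCol("qValue", rep(-1, n)))
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
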