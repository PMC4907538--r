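# Readers and writers for the plain-text interchange formats.
# All files are BED-style: tab-separated, 0-based half-open coordinates.
# GRanges objects in memory are 1-based closed; conversion happens here
# and only here.

.bed2gr <- function(df, seqinfo = NULL) {
  GRanges(df[[1]], IRanges(start = df[[2]] + 1L, end = df[[3]]),
          seqinfo = seqinfo)
}

.gr2bed <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr),
             stringsAsFactors = FALSE)
}

.readTsv <- function(path, what, minCols) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               quote = "", stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", what, " file '", path,
                             "': ", conditionMessage(e)))
  if (ncol(df) < minCols)
    stop(what, " file '", path, "' needs at least ", minCols, " columns")
  df
}

.checkIntervals <- function(df, what) {
  if (!is.numeric(df[[2]]) || !is.numeric(df[[3]]))
    stop(what, ": start/end columns must be numeric")
  bad <- which(!(df[[2]] >= 0 & df[[2]] < df[[3]]))
  if (length(bad))
    stop(what, ": malformed interval (need 0 <= start < end) at line(s) ",
         paste(head(bad, 5), collapse = ", "))
}

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with columns chromosome name, length (bp).
#' @return named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- .readTsv(path, "chromosome sizes", 2)
  setNames(as.integer(df[[2]]), as.character(df[[1]]))
}

#' Read a fragment-level chromatin-state map
#'
#' Reads a 4-column interval file (chrom, start, end, state; 0-based
#' half-open) into a [ChromatinMap-class]. Non-gap fragments must be
#' exactly 200 bp long and non-overlapping; legacy color labels
#' (cyan/blue/green/magenta) are accepted. Uncovered stretches between
#' the declared chromosome bounds are materialized as \code{gap}
#' fragments, so the returned map tiles every chromosome completely.
#'
#' @param path path to the fragment file.
#' @param chromSizes named vector of chromosome lengths, or a path to a
#'   2-column sizes TSV. If \code{NULL}, each chromosome's length is taken
#'   as the end of its last fragment.
#' @param fragmentLength expected non-gap fragment length (bp); set to
#'   \code{NA} to skip the check.
#' @return a [ChromatinMap-class] (domains empty).
#' @examples
#' tf <- tempfile()
#' writeLines(c("2L\t0\t200\truby", "2L\t200\t400\truby",
#'              "2L\t400\t600\tmalachite"), tf)
#' readStateMap(tf, chromSizes = c(`2L` = 1000))
#' @export
readStateMap <- function(path, chromSizes = NULL, fragmentLength = 200) {
  df <- .readTsv(path, "state map", 4)
  .checkIntervals(df, "state map")
  state <- .normalizeStates(df[[4]])
  if (!is.na(fragmentLength)) {
    w <- df[[3]] - df[[2]]
    bad <- which(state != "gap" & w != fragmentLength)
    if (length(bad))
      stop("state map: non-gap fragment not ", fragmentLength,
           " bp at line(s) ", paste(head(bad, 5), collapse = ", "))
  }
  # overlap check with line numbers, per chromosome
  ord <- order(df[[1]], df[[2]])
  sameChrom <- df[[1]][ord][-1] == df[[1]][ord][-length(ord)]
  ovl <- sameChrom & (df[[2]][ord][-1] < df[[3]][ord][-length(ord)])
  if (any(ovl))
    stop("state map: overlapping fragments at line(s) ",
         paste(head(ord[-1][ovl], 5), collapse = ", "))
  if (is.character(chromSizes) && length(chromSizes) == 1L)
    chromSizes <- readChromSizes(chromSizes)
  if (is.null(chromSizes))
    chromSizes <- tapply(df[[3]], df[[1]], max)
  gr <- .bed2gr(df)
  gr$state <- state
  ChromatinMap(gr, chromLengths = chromSizes)
}

#' Read IH regions (BED4; name = cytological band label)
#'
#' @param path BED4 file: chrom, start, end, band name.
#' @param seqinfo optional [GenomeInfoDb::Seqinfo] to attach.
#' @return [GenomicRanges::GRanges] with a \code{name} column, sorted;
#'   regions on one chromosome must be non-overlapping.
#' @export
readRegions <- function(path, seqinfo = NULL) {
  df <- .readTsv(path, "regions", 4)
  .checkIntervals(df, "regions")
  gr <- .bed2gr(df, seqinfo)
  gr$name <- as.character(df[[4]])
  gr <- sort(gr, ignore.strand = TRUE)
  if (any(width(reduce(gr, ignore.strand = TRUE)) != width(gr)) ||
      length(reduce(gr, ignore.strand = TRUE)) != length(gr))
    stop("regions: overlapping regions on one chromosome")
  gr
}

#' Read an annotation track (BED3 or BED5)
#'
#' Column 4 (name) is ignored; column 5, when present, is kept as
#' \code{score} (e.g. a peak read count). Intervals are sorted but not
#' merged here; length-accounting operations merge internally.
#'
#' @param path BED file.
#' @param seqinfo optional Seqinfo.
#' @return sorted [GenomicRanges::GRanges], with \code{score} if present.
#' @export
readTrack <- function(path, seqinfo = NULL) {
  df <- .readTsv(path, "track", 3)
  .checkIntervals(df, "track")
  gr <- .bed2gr(df, seqinfo)
  if (ncol(df) >= 5) gr$score <- as.numeric(df[[5]])
  sort(gr, ignore.strand = TRUE)
}

#' Read a reference genome partition (BED4; name = class label)
#'
#' A partition labels the genome with non-overlapping typed intervals,
#' e.g. the 5-color model, a 9-state segmentation, or the 3-class
#' compactization map.
#'
#' @param path BED4 file: chrom, start, end, class label.
#' @param seqinfo optional Seqinfo.
#' @return sorted [GenomicRanges::GRanges] with a \code{class} column.
#' @export
readPartition <- function(path, seqinfo = NULL) {
  df <- .readTsv(path, "partition", 4)
  .checkIntervals(df, "partition")
  gr <- .bed2gr(df, seqinfo)
  gr$class <- as.character(df[[4]])
  gr <- sort(gr, ignore.strand = TRUE)
  if (sum(as.numeric(width(reduce(gr, ignore.strand = TRUE)))) !=
      sum(as.numeric(width(gr))))
    stop("partition: classes must be non-overlapping")
  gr
}

#' Read replication-timing probes (BED with score column)
#'
#' @param path BED file with at least 4 columns; the score is read from
#'   column 5 if present, else column 4.
#' @param seqinfo optional Seqinfo.
#' @return sorted [GenomicRanges::GRanges] with a numeric \code{score}
#'   (positive = early, negative = late replication).
#' @export
readProbes <- function(path, seqinfo = NULL) {
  df <- .readTsv(path, "probes", 4)
  .checkIntervals(df, "probes")
  gr <- .bed2gr(df, seqinfo)
  scoreCol <- if (ncol(df) >= 5 && is.numeric(df[[5]])) 5L else 4L
  if (!is.numeric(df[[scoreCol]]))
    stop("probes: no numeric score column found")
  gr$score <- as.numeric(df[[scoreCol]])
  sort(gr, ignore.strand = TRUE)
}

#' Write merged chromatin domains as BED4 + fragment count
#'
#' Columns: chrom, start, end, state, n_fragments (0-based half-open).
#'
#' @param map a [ChromatinMap-class] with merged domains.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeDomains <- function(map, path) {
  dm <- chromatinDomains(map)
  if (!length(dm)) stop("map has no merged domains; run mergeDomains()")
  df <- cbind(.gr2bed(dm),
              state = as.character(dm$state),
              n_fragments = dm$nFragments)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a fragment-level map (BED4), gaps included
#'
#' @param map a [ChromatinMap-class].
#' @param path output path.
#' @param gaps include explicit gap rows (default \code{TRUE}).
#' @return invisibly, the path.
#' @export
writeStateMap <- function(map, path, gaps = TRUE) {
  fr <- stateFragments(map)
  if (!gaps) fr <- fr[fr$state != "gap"]
  df <- cbind(.gr2bed(fr), state = as.character(fr$state))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.writeBed <- function(gr, path, extra = NULL) {
  df <- .gr2bed(gr)
  if (!is.null(extra)) df <- cbind(df, extra)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
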