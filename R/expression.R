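# Expression breadth and magnitude by chromatin class. Transcript-level
# records carry the RPKM of their gene across 29 adult/larval tissues
# plus cell lines; a transcript is assigned to the chromatin class whose
# per-base state contains its TSS.

#' Read a transcript expression table
#'
#' Simplified TSV layout (with header): \code{gene_id}, \code{transcript_id},
#' \code{chrom}, \code{strand}, \code{tss} (0-based base position; the
#' annotated transcription start, i.e. the start coordinate of + strand
#' and the end coordinate of - strand transcripts), then one numeric RPKM
#' column per sample. An optional sample manifest (TSV with header:
#' \code{sample}, \code{group}) classifies columns as \code{tissue} or
#' \code{cell_line}; without it all samples count as tissues.
#'
#' @param path transcript TSV.
#' @param manifest optional path to the sample manifest.
#' @return a [SummarizedExperiment::RangedSummarizedExperiment] with a
#'   1-bp TSS \code{rowRanges} (columns \code{gene_id},
#'   \code{transcript_id}), assay \code{"rpkm"}, and a \code{group}
#'   column in \code{colData}.
#' @export
readTranscripts <- function(path, manifest = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "transcript_id", "chrom", "strand", "tss")
  if (!all(need %in% names(df)))
    stop("transcript table must have columns: ",
         paste(need, collapse = ", "))
  samples <- setdiff(names(df), need)
  if (!length(samples)) stop("no RPKM sample columns found")
  rpkm <- as.matrix(df[, samples, drop = FALSE])
  if (any(rpkm < 0)) stop("RPKM values must be non-negative")
  rr <- GRanges(df$chrom,
                IRanges(start = df$tss + 1L, width = 1L),
                strand = df$strand)
  rr$gene_id <- df$gene_id
  rr$transcript_id <- df$transcript_id
  group <- rep("tissue", length(samples))
  if (!is.null(manifest)) {
    mf <- read.table(manifest, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    group <- mf$group[match(samples, mf$sample)]
    group[is.na(group)] <- "tissue"
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = rpkm), rowRanges = rr,
    colData = DataFrame(sample = samples, group = group,
                        row.names = samples))
}

#' Assign transcripts to chromatin classes by TSS position
#'
#' Each transcript gets the chromatin class whose (half-open) span
#' contains its TSS base; TSSs in residual gaps are \code{"unassigned"}.
#' When border/internal malachite labels are supplied (from
#' [classifyMalachite()]), TSSs inside those IH malachite domains are
#' refined to \code{"malachite_border"} / \code{"malachite_internal"}.
#'
#' @param transcripts a \code{RangedSummarizedExperiment} from
#'   [readTranscripts()] (or a TSS \code{GRanges}).
#' @param map a [ChromatinMap-class].
#' @param malachiteLabels optional labelled malachite \code{GRanges} from
#'   [classifyMalachite()].
#' @return character vector of class labels, one per transcript.
#' @export
assignTssClass <- function(transcripts, map, malachiteLabels = NULL) {
  tss <- if (is(transcripts, "SummarizedExperiment"))
    SummarizedExperiment::rowRanges(transcripts) else transcripts
  tss <- granges(tss)
  strand(tss) <- "*"
  fr <- stateFragments(map)
  sl <- chromLengths(map)
  chrom <- as.character(seqnames(tss))
  if (any(!chrom %in% names(sl)) ||
      any(start(tss) < 1 | start(tss) > sl[chrom]))
    stop("TSS outside the map bounds")
  ht <- findOverlaps(tss, fr, ignore.strand = TRUE, select = "first")
  cls <- rep("unassigned", length(tss))
  hit <- !is.na(ht)
  cls[hit] <- as.character(fr$state[ht[hit]])
  cls[cls == "gap"] <- "unassigned"
  if (!is.null(malachiteLabels) && length(malachiteLabels)) {
    hm <- findOverlaps(tss, malachiteLabels, ignore.strand = TRUE,
                       select = "first")
    inMal <- !is.na(hm) & cls == "malachite"
    cls[inMal] <- paste0("malachite_", malachiteLabels$label[hm[inMal]])
  }
  cls
}

#' Expression breadth: number of tissues where a gene is expressed
#'
#' A transcript is expressed in a tissue when its RPKM is strictly above
#' the threshold; RPKM exactly at the threshold counts as silent
#' (silent = RPKM <= threshold). Breadth is monotone non-increasing in
#' the threshold.
#'
#' @param x a \code{RangedSummarizedExperiment} from [readTranscripts()]
#'   or an RPKM matrix (transcripts x samples).
#' @param threshold expressed/silent RPKM cutoff (default 3).
#' @param tissuesOnly with a \code{SummarizedExperiment}, restrict to
#'   columns with \code{group == "tissue"} (default \code{TRUE}).
#' @return integer vector: tissues expressed per transcript.
#' @export
expressionBreadth <- function(x, threshold = 3, tissuesOnly = TRUE) {
  if (is(x, "SummarizedExperiment")) {
    keep <- if (tissuesOnly) x$group == "tissue" else rep(TRUE, ncol(x))
    m <- SummarizedExperiment::assay(x, "rpkm")[, keep, drop = FALSE]
  } else m <- x
  as.integer(rowSums(m > threshold))
}

#' Quartiles and 12.5/87.5 percentile whiskers
#'
#' Five-number expression summary: Q1/Q2/Q3 with whiskers at the 12.5th
#' and 87.5th percentiles, computed with the linear-interpolation
#' percentile convention (\code{stats::quantile} \code{type = 7} by
#' default; configurable).
#'
#' @param values numeric vector (must be non-empty).
#' @param type quantile algorithm passed to \code{stats::quantile}.
#' @return named numeric vector \code{p12.5, q1, q2, q3, p87.5}.
#' @export
expressionQuartiles <- function(values, type = 7) {
  if (!length(values)) stop("empty class: no values to summarise")
  q <- quantile(values, probs = c(.125, .25, .5, .75, .875),
                type = type, names = FALSE)
  setNames(q, c("p12.5", "q1", "q2", "q3", "p87.5"))
}

#' Per-class expression summary
#'
#' For each chromatin class: the breadth distribution summary (median
#' tissues expressed) and the quartile/whisker summary of a per-gene
#' expression magnitude (by default the RPKM summed over tissue
#' samples).
#'
#' @param x \code{RangedSummarizedExperiment} from [readTranscripts()].
#' @param classes class label per transcript (from [assignTssClass()]).
#' @param threshold expressed/silent RPKM cutoff.
#' @param magnitude function reducing a transcript's tissue RPKM vector
#'   to one number (default \code{sum}).
#' @return \code{data.frame}: one row per class with \code{n},
#'   \code{medianBreadth}, and the five magnitude percentiles.
#' @export
expressionSummary <- function(x, classes, threshold = 3,
                              magnitude = sum) {
  stopifnot(length(classes) == nrow(x))
  breadth <- expressionBreadth(x, threshold = threshold)
  keep <- x$group == "tissue"
  mag <- apply(SummarizedExperiment::assay(x, "rpkm")[, keep,
                                                      drop = FALSE],
               1, magnitude)
  cls <- sort(unique(classes))
  rows <- lapply(cls, function(cl) {
    i <- classes == cl
    data.frame(class = cl, n = sum(i),
               medianBreadth = median(breadth[i]),
               t(expressionQuartiles(mag[i])),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
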