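#' Total overlap length between two interval sets
#'
#' Both sets are merged (union within each set) before intersection, so
#' overlapping ChIP regions are not double-counted; the result is the bp
#' size of the set intersection and is symmetric in its arguments.
#'
#' @param a,b [GenomicRanges::GRanges].
#' @return total overlap in bp (numeric).
#' @export
overlapLength <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  a <- reduce(granges(a), ignore.strand = TRUE)
  b <- reduce(granges(b), ignore.strand = TRUE)
  suppressWarnings(
    sum(as.numeric(width(GenomicRanges::intersect(a, b,
                                                  ignore.strand = TRUE)))))
}

#' Overlap profile of a query class against a reference partition
#'
#' Fraction of query bp falling into each class of a reference genome
#' partition (5-color, 9-state, 3-class compactization, ...). The
#' remainder is reported as \code{"unannotated"}; fractions including it
#' sum to 1.
#'
#' @param query \code{GRanges} of one chromatin class.
#' @param partition \code{GRanges} with a \code{class} column; classes
#'   must be non-overlapping (see [readPartition()]).
#' @return \code{data.frame} with \code{reference}, \code{bp},
#'   \code{fraction}.
#' @export
overlapProfile <- function(query, partition) {
  qbp <- sum(as.numeric(width(reduce(granges(query),
                                     ignore.strand = TRUE))))
  classes <- unique(as.character(partition$class))
  bp <- vapply(classes, function(cl)
    overlapLength(query, partition[partition$class == cl]), numeric(1))
  bp <- c(bp, unannotated = qbp - sum(bp))
  data.frame(reference = names(bp), bp = unname(bp),
             fraction = if (qbp > 0) unname(bp) / qbp else unname(bp) * 0,
             stringsAsFactors = FALSE)
}

#' Observed/expected density ratio of a track within a query class
#'
#' The observed fraction is total track overlap divided by query bp. The
#' expected fraction is, by default, the mean of the shuffle-null overlap
#' divided by query bp (pass \code{nullMean} from a
#' [ShuffleResult-class]); without it, the genome-wide track density over
#' \code{genomeLength} is used as fallback. Ratios above 1 indicate
#' enrichment of the track in the query class.
#'
#' @param query \code{GRanges} of the chromatin class under test.
#' @param track annotation track \code{GRanges} (merged internally).
#' @param nullMean mean overlap bp under the shuffle null, or \code{NULL}.
#' @param genomeLength total genome span (bp) for the density fallback;
#'   required when \code{nullMean} is \code{NULL}.
#' @return \code{list} with \code{observed}, \code{expected},
#'   \code{ratio}.
#' @export
densityRatio <- function(query, track, nullMean = NULL,
                         genomeLength = NULL) {
  qbp <- sum(as.numeric(width(reduce(granges(query),
                                     ignore.strand = TRUE))))
  if (qbp == 0) stop("query has zero length")
  observed <- overlapLength(query, track) / qbp
  expected <- if (!is.null(nullMean)) {
    nullMean / qbp
  } else {
    if (is.null(genomeLength))
      stop("need nullMean or genomeLength for the expected fraction")
    sum(as.numeric(width(reduce(granges(track),
                                ignore.strand = TRUE)))) / genomeLength
  }
  list(observed = observed, expected = expected,
       ratio = if (expected > 0) observed / expected
               else if (observed == 0) 0 else Inf)
}

#' Peak density per chromatin state, stratified by read count
#'
#' Bins scored peaks (e.g. stalled RNA Pol II short-transcript peaks) by
#' read count and reports, per bin and state, the number of peaks
#' overlapping that state divided by the state's total length in Mb. A
#' peak overlapping two states (straddling a boundary) counts for both.
#'
#' @param peaks \code{GRanges} with a numeric \code{score} (read count).
#' @param map a [ChromatinMap-class] with merged domains, or a domain
#'   \code{GRanges} with \code{state}.
#' @param bins numeric vector of bin edges for the read counts; default
#'   logarithmic edges covering the score range.
#' @return \code{data.frame} with \code{bin} (label), \code{binLow},
#'   \code{binHigh}, \code{state}, \code{count}, \code{densityPerMb}.
#' @export
peakDensityByReadCount <- function(peaks, map, bins = NULL) {
  if (is.null(peaks$score) || anyNA(peaks$score))
    stop("peaks must carry a complete numeric score (read count)")
  dm <- .domainsOf(map)
  stateBp <- tapply(as.numeric(width(dm)), dm$state, sum, default = 0)
  stateBp <- setNames(as.numeric(stateBp[chromatinStates()]),
                      chromatinStates())
  stateBp[is.na(stateBp)] <- 0
  if (is.null(bins)) {
    hi <- max(peaks$score, 1)
    bins <- unique(c(0, 2^(0:ceiling(log2(hi + 1)))))
  }
  cuts <- cut(peaks$score, breaks = bins, include.lowest = TRUE)
  out <- expand.grid(bin = levels(cuts), state = chromatinStates(),
                     stringsAsFactors = FALSE)
  out$binLow <- bins[match(out$bin, levels(cuts))]
  out$binHigh <- bins[match(out$bin, levels(cuts)) + 1L]
  out$count <- 0L
  if (length(peaks)) {
    ht <- findOverlaps(peaks, dm, ignore.strand = TRUE)
    if (length(ht)) {
      hitState <- as.character(dm$state[subjectHits(ht)])
      # a peak spanning several domains of one state still counts once
      key <- unique(paste(queryHits(ht), hitState))
      qh <- as.integer(sub(" .*", "", key))
      st <- sub("^[0-9]+ ", "", key)
      tb <- table(bin = cuts[qh], state = st)
      idx <- cbind(match(out$bin, rownames(tb)),
                   match(out$state, colnames(tb)))
      ok <- complete.cases(idx)
      out$count[ok] <- as.integer(tb[idx[ok, , drop = FALSE]])
    }
  }
  out$densityPerMb <- ifelse(stateBp[out$state] > 0,
                             out$count / (stateBp[out$state] / 1e6), NA)
  out[order(out$binLow, out$state), ]
}
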