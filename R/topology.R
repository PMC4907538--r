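#' Contact matrix between chromatin states
#'
#' Counts adjacencies between consecutive chromatin domains along each
#' chromosome. In \code{"opaque"} mode (default) only directly abutting
#' domains count as a contact; in \code{"transparent"} mode pairs
#' separated by residual unassigned gap of at most \code{maxSpan} bp also
#' count. The result is a symmetric state-by-state table of contact
#' counts; each adjacent pair is counted once.
#'
#' After merging, directly abutting domains never share a state, so the
#' diagonal can only be populated in transparent mode (same-state domains
#' separated by an unfilled gap).
#'
#' @param map a [ChromatinMap-class] with merged domains.
#' @param gapMode \code{"opaque"} or \code{"transparent"}.
#' @param maxSpan maximum intervening gap (bp) in transparent mode.
#' @return symmetric 4x4 integer matrix of contact counts with
#'   \code{attr(., "total")} = number of pairs counted.
#' @export
contactMatrix <- function(map, gapMode = c("opaque", "transparent"),
                          maxSpan = Inf) {
  gapMode <- match.arg(gapMode)
  dm <- .domainsOf(map)
  states <- chromatinStates()
  m <- matrix(0L, 4, 4, dimnames = list(states, states))
  if (length(dm) >= 2) {
    dm <- sort(dm, ignore.strand = TRUE)
    n <- length(dm)
    i <- 1:(n - 1)
    sameChrom <- as.character(seqnames(dm))[i] ==
      as.character(seqnames(dm))[i + 1]
    gap <- start(dm)[i + 1] - end(dm)[i] - 1L
    keep <- sameChrom & if (gapMode == "opaque") gap == 0L
                        else gap <= maxSpan
    a <- as.character(dm$state)[i][keep]
    b <- as.character(dm$state)[i + 1][keep]
    for (k in seq_along(a)) {
      m[a[k], b[k]] <- m[a[k], b[k]] + 1L
      if (a[k] != b[k]) m[b[k], a[k]] <- m[b[k], a[k]] + 1L
    }
    attr(m, "total") <- length(a)
  } else attr(m, "total") <- 0L
  m
}

#' Classify IH malachite domains as border or internal
#'
#' A malachite domain overlapping an IH region is a \emph{border}
#' malachite when its span touches or crosses a region boundary (within
#' \code{tolerance} bp); otherwise it is \emph{internal}. Border
#' malachite is the transition zone between the repressed ruby core of an
#' IH band and the active flanking interband; internal malachite is
#' embedded in the band.
#'
#' @param map a [ChromatinMap-class] with merged domains, or a domain
#'   \code{GRanges} with \code{state}.
#' @param regions IH region \code{GRanges} with \code{name}.
#' @param tolerance slack (bp) around the region boundary; default 0.
#' @param minOverlap membership threshold (bp).
#' @return \code{GRanges} of whole malachite domains overlapping the
#'   regions, with columns \code{label} (\code{"border"}/
#'   \code{"internal"}) and \code{region}. Every such domain receives
#'   exactly one label; a domain overlapping several regions is assigned
#'   to the one it overlaps most.
#' @export
classifyMalachite <- function(map, regions, tolerance = 0, minOverlap = 1) {
  dm <- .domainsOf(map)
  dm <- dm[dm$state == "malachite"]
  ht <- findOverlaps(dm, regions, minoverlap = minOverlap,
                     ignore.strand = TRUE)
  if (length(ht)) {
    ov <- width(pintersect(dm[queryHits(ht)], regions[subjectHits(ht)],
                           ignore.strand = TRUE))
    # one label per domain: keep the region with the largest overlap
    best <- tapply(seq_along(ov), queryHits(ht),
                   function(ii) ii[which.max(ov[ii])])
    ht <- ht[as.integer(best)]
  }
  d <- dm[queryHits(ht)]
  r <- regions[subjectHits(ht)]
  # boundary coordinates in 0-based half-open terms
  ds <- start(d) - 1; de <- end(d)
  rs <- start(r) - 1; re <- end(r)
  border <- (rs >= ds - tolerance & rs <= de + tolerance) |
            (re >= ds - tolerance & re <= de + tolerance)
  d$label <- ifelse(border, "border", "internal")
  d$region <- if (!is.null(r$name)) r$name else as.character(subjectHits(ht))
  d
}

#' Summary statistics for domains of one state within regions
#'
#' @param map a [ChromatinMap-class] with merged domains or a domain
#'   \code{GRanges}.
#' @param state chromatin state to summarise.
#' @param regions optional region \code{GRanges}; when given, only
#'   domains overlapping the regions are summarised.
#' @param clipped measure clipped in-region lengths instead of whole
#'   domain lengths (default \code{FALSE}: whole domains, one entry per
#'   domain).
#' @param minOverlap membership threshold (bp).
#' @return \code{list} with \code{count}, \code{meanLength},
#'   \code{medianLength}, \code{totalBp}, \code{nRegions} (regions
#'   containing at least one such domain; \code{NA} without regions) and
#'   \code{empty} flag (\code{TRUE} when count is 0 and the means are
#'   undefined).
#' @export
domainStats <- function(map, state, regions = NULL, clipped = FALSE,
                        minOverlap = 1) {
  dm <- .domainsOf(map)
  dm <- dm[as.character(dm$state) == state]
  nRegions <- NA_integer_
  if (is.null(regions)) {
    len <- as.numeric(width(dm))
  } else {
    seg <- clipToRegions(dm, regions, minOverlap = minOverlap)
    nRegions <- length(unique(seg$region))
    len <- if (clipped) as.numeric(width(seg))
           else as.numeric(tapply(seg$parentEnd - seg$parentStart + 1,
                                  seg$parent, function(x) x[1]))
  }
  n <- length(len)
  list(count = n,
       meanLength = if (n) mean(len) else NA_real_,
       medianLength = if (n) median(len) else NA_real_,
       totalBp = sum(len),
       nRegions = nRegions,
       empty = n == 0L)
}
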