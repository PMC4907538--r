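#' ChromatinMap: a fragment-level chromatin-state map with merged domains
#'
#' Container for a whole-genome four-state chromatin map. The
#' \code{fragments} slot tiles every declared chromosome completely with
#' typed fragments: non-gap fragments carry one of the four chromatin
#' states, and unassigned sequence is materialized as explicit \code{gap}
#' fragments, so per-base state assignment is total. The \code{domains}
#' slot holds maximal runs of same-state abutting fragments after
#' [mergeDomains()]; it is empty until then.
#'
#' Coordinates are stored as 1-based closed [GenomicRanges::GRanges];
#' on-disk interchange uses 0-based half-open BED-style files (see
#' [readStateMap()], [writeDomains()]).
#'
#' @slot fragments [GenomicRanges::GRanges] with metadata column
#'   \code{state} (factor over [chromatinLevels()]); sorted,
#'   non-overlapping, tiling each chromosome of the declared
#'   \code{seqlengths} exactly.
#' @slot domains [GenomicRanges::GRanges] with metadata columns
#'   \code{state} (non-gap) and \code{nFragments} (number of fragments
#'   merged into the domain).
#'
#' @seealso [readStateMap()], [fillGaps()], [mergeDomains()], [genMap()]
#' @export
setClass("ChromatinMap",
  slots = c(fragments = "GRanges", domains = "GRanges"))

setValidity("ChromatinMap", function(object) {
  fr <- object@fragments
  msgs <- character()
  if (is.null(fr$state))
    return("fragments must carry a 'state' metadata column")
  if (!all(levels(fr$state) == chromatinLevels()))
    msgs <- c(msgs, "fragment state levels must equal chromatinLevels()")
  sl <- seqlengths(fr)
  if (any(is.na(sl)))
    msgs <- c(msgs, "all chromosome lengths must be declared (seqlengths)")
  if (is.unsorted(order(as.integer(seqnames(fr)), start(fr))))
    msgs <- c(msgs, "fragments must be sorted")
  # total tiling: fragment widths sum to declared lengths per chromosome
  if (length(fr) && !any(is.na(sl))) {
    w <- tapply(width(fr), as.character(seqnames(fr)), sum)
    covered <- setNames(rep(0, length(sl)), names(sl))
    covered[names(w)] <- w
    if (!all(covered == sl))
      msgs <- c(msgs, "fragments (incl. gaps) must tile each chromosome exactly")
    if (any(width(disjoin(fr)) != width(sort(fr))))
      msgs <- c(msgs, "fragments must be non-overlapping")
  }
  dm <- object@domains
  if (length(dm)) {
    if (is.null(dm$state) || is.null(dm$nFragments))
      msgs <- c(msgs, "domains must carry 'state' and 'nFragments'")
    else if (any(as.character(dm$state) == "gap"))
      msgs <- c(msgs, "domains must not be gaps")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ChromatinMap from typed fragments
#'
#' @param fragments a [GenomicRanges::GRanges] with a \code{state} column
#'   (character or factor; legacy color labels accepted).
#' @param chromLengths named numeric vector of chromosome lengths. If
#'   missing, taken from \code{seqlengths(fragments)}.
#' @param fillUncovered materialize uncovered stretches between declared
#'   chromosome bounds as \code{gap} fragments (default \code{TRUE}).
#' @return a [ChromatinMap-class] object (domains empty).
#' @export
ChromatinMap <- function(fragments, chromLengths = NULL,
                         fillUncovered = TRUE) {
  fragments$state <- .normalizeStates(fragments$state)
  if (is.null(chromLengths)) {
    chromLengths <- seqlengths(fragments)
    if (any(is.na(chromLengths)))
      stop("chromLengths missing and seqlengths(fragments) undeclared")
  }
  fragments <- GRanges(seqnames(fragments), ranges(fragments),
                       state = fragments$state,
                       seqinfo = Seqinfo(names(chromLengths),
                                         as.integer(chromLengths)))
  fragments <- sort(fragments, ignore.strand = TRUE)
  if (fillUncovered)
    fragments <- .materializeGaps(fragments)
  new("ChromatinMap", fragments = fragments,
      domains = .emptyDomains(seqinfo(fragments)))
}

.emptyDomains <- function(si) {
  gr <- GRanges(seqinfo = si)
  mcols(gr) <- DataFrame(state = factor(character(),
                                        levels = chromatinStates()),
                         nFragments = integer())
  gr
}

# fill uncovered sequence with explicit gap fragments; merge adjacent gaps
.materializeGaps <- function(fr) {
  covered <- reduce(fr, ignore.strand = TRUE)
  gp <- gaps(covered)
  gp <- gp[strand(gp) == "*"]
  if (length(gp)) {
    gp$state <- factor("gap", levels = chromatinLevels())
    fr <- sort(c(fr, gp), ignore.strand = TRUE)
  }
  # consolidate runs of abutting gap fragments into one
  isGap <- fr$state == "gap"
  if (any(isGap)) {
    gapRed <- reduce(fr[isGap], ignore.strand = TRUE)
    gapRed$state <- factor("gap", levels = chromatinLevels())
    fr <- sort(c(fr[!isGap], gapRed), ignore.strand = TRUE)
  }
  fr
}

#' Arrangement: ordered domain and spacer lengths on one chromosome
#'
#' The object the permutation test shuffles. For one chromatin type on one
#' chromosome, the N domain lengths \code{An} in chromosomal order and the
#' N+1 spacer lengths \code{Sn}, where S1 runs from the chromosome start
#' to the first domain and S(N+1) from the last domain to the chromosome
#' end. Spacers may have zero length; the two length multisets together
#' always sum to the chromosome length.
#'
#' @slot chrom chromosome name.
#' @slot chromLength chromosome length in bp.
#' @slot domainLengths numeric vector of domain lengths (bp), in order.
#' @slot spacerLengths numeric vector of N+1 spacer lengths (bp), in order.
#' @seealso [decomposeArrangement()], [shuffleArrangement()]
#' @export
setClass("Arrangement",
  slots = c(chrom = "character", chromLength = "numeric",
            domainLengths = "numeric", spacerLengths = "numeric"))

setValidity("Arrangement", function(object) {
  msgs <- character()
  A <- object@domainLengths; S <- object@spacerLengths
  if (length(S) != length(A) + 1L)
    msgs <- c(msgs, "need exactly N+1 spacers for N domains")
  if (any(A <= 0))
    msgs <- c(msgs, "domain lengths must be positive")
  if (any(S < 0))
    msgs <- c(msgs, "spacer lengths must be non-negative")
  if (!isTRUE(all.equal(sum(A) + sum(S), object@chromLength)))
    msgs <- c(msgs, "domain + spacer lengths must sum to the chromosome length")
  if (length(msgs)) msgs else TRUE
})

#' ShuffleResult: outcome of a domain-shuffle permutation test
#'
#' Holds the observed track-overlap statistic, a summary of the
#' Monte-Carlo null, both one-sided empirical p-values (ties counted as
#' extreme on both sides, so \code{countGE + countLE >= M}), add-one
#' estimators, and the method actually used: \code{"empirical"} or
#' \code{"normal_approx"} (Gaussian tail on the null mean/sd, used when an
#' empirical p of exactly 0 or 1 was obtained and the null is not
#' degenerate).
#'
#' @slot chrom chromosome name, or \code{"genome"} for a joint test.
#' @slot statistic \code{"length"} (total overlap bp) or \code{"count"}
#'   (number of domains overlapping the track).
#' @slot observed observed statistic.
#' @slot nullMean,nullSd moments of the Monte-Carlo null sample.
#' @slot M number of shuffle iterations.
#' @slot countGE,countLE null draws \code{>=} / \code{<=} the observed.
#' @slot pEnrich,pDeplete one-sided p-values as reported (empirical
#'   count/M, or Gaussian tail when that count was 0 or M).
#' @slot pEnrichAdd1,pDepleteAdd1 (count+1)/(M+1) estimators.
#' @slot method \code{"empirical"} or \code{"normal_approx"}.
#' @slot degenerate \code{TRUE} when the null sd is zero (p-values are
#'   then empirical by necessity).
#' @export
setClass("ShuffleResult",
  slots = c(chrom = "character", statistic = "character",
            observed = "numeric", nullMean = "numeric", nullSd = "numeric",
            M = "numeric", countGE = "numeric", countLE = "numeric",
            pEnrich = "numeric", pDeplete = "numeric",
            pEnrichAdd1 = "numeric", pDepleteAdd1 = "numeric",
            method = "character", degenerate = "logical"))

setValidity("ShuffleResult", function(object) {
  msgs <- character()
  if (object@M < 1) msgs <- c(msgs, "M must be >= 1")
  p <- c(object@pEnrich, object@pDeplete)
  if (any(p < 0 | p > 1)) msgs <- c(msgs, "p-values must lie in [0, 1]")
  if (object@countGE + object@countLE < object@M)
    msgs <- c(msgs, "ties must be counted on both sides (countGE+countLE >= M)")
  if (!object@method %in% c("empirical", "normal_approx"))
    msgs <- c(msgs, "method must be 'empirical' or 'normal_approx'")
  if (length(msgs)) msgs else TRUE
})
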