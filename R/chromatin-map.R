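#' Fill short unassigned gaps flanked by a single chromatin type
#'
#' A gap fragment of length at most \code{maxGap} whose immediate non-gap
#' neighbours on both sides carry the same state is relabelled to that
#' state. All other fragments are unchanged; coordinates are never
#' touched; the rule is applied in a single pass (a relabelled gap may
#' unite two runs — [mergeDomains()] handles that — but no second round
#' of filling is performed across newly united material). Gaps at
#' chromosome ends have a single flank and are never relabelled. The
#' operation is idempotent.
#'
#' @param map a [ChromatinMap-class].
#' @param maxGap maximum gap length to fill (bp, default 400; the
#'   boundary value is inclusive).
#' @return a [ChromatinMap-class] with relabelled gap fragments (domains
#'   reset to empty).
#' @examples
#' fr <- GenomicRanges::GRanges("2L", IRanges::IRanges(
#'          c(1, 201, 601), c(200, 600, 800)),
#'        state = c("malachite", "gap", "malachite"))
#' m <- ChromatinMap(fr, chromLengths = c(`2L` = 800))
#' table(stateFragments(fillGaps(m))$state)
#' @export
fillGaps <- function(map, maxGap = 400) {
  stopifnot(is(map, "ChromatinMap"))
  fr <- stateFragments(map)
  st <- as.character(fr$state)
  chrom <- as.character(seqnames(fr))
  n <- length(fr)
  if (n >= 3) {
    i <- 2:(n - 1)
    # fragments tile each chromosome, so within-chromosome neighbours abut;
    # consecutive gaps are consolidated at construction, hence the
    # immediate neighbours of a gap are non-gap on the same chromosome
    fill <- st[i] == "gap" &
      chrom[i - 1] == chrom[i] & chrom[i + 1] == chrom[i] &
      st[i - 1] != "gap" & st[i + 1] != "gap" &
      st[i - 1] == st[i + 1] &
      width(fr)[i] <= maxGap
    idx <- i[fill]
    st[idx] <- st[idx - 1]
  }
  fr$state <- factor(st, levels = chromatinLevels())
  # valid by construction (labels changed, coordinates untouched)
  S4Vectors::new2("ChromatinMap", fragments = fr,
                  domains = .emptyDomains(seqinfo(fr)), check = FALSE)
}

#' Merge same-state fragment runs into chromatin domains
#'
#' Maximal runs of abutting fragments sharing one non-gap state become a
#' single domain; residual gaps break runs. Per-base state assignment is
#' preserved exactly: the union of domains and residual gaps reconstructs
#' the fragment map.
#'
#' @param map a [ChromatinMap-class] (normally after [fillGaps()]).
#' @return the map with its \code{domains} slot populated; each domain
#'   carries \code{state} and \code{nFragments}, the number of fragments
#'   merged into it.
#' @export
mergeDomains <- function(map) {
  stopifnot(is(map, "ChromatinMap"))
  fr <- stateFragments(map)
  key <- paste(as.character(seqnames(fr)), as.character(fr$state))
  r <- Rle(key)
  runEnd <- cumsum(runLength(r))
  runStart <- runEnd - runLength(r) + 1L
  dm <- GRanges(seqnames(fr)[runStart],
                IRanges(start(fr)[runStart], end(fr)[runEnd]),
                seqinfo = seqinfo(fr))
  dm$state <- fr$state[runStart]
  dm$nFragments <- runLength(r)
  keep <- dm$state != "gap"
  dm <- dm[keep]
  dm$state <- factor(as.character(dm$state), levels = chromatinStates())
  # valid by construction (fragments unchanged, domains from their runs)
  S4Vectors::new2("ChromatinMap", fragments = fr, domains = dm,
                  check = FALSE)
}

.domainsOf <- function(x) {
  if (is(x, "ChromatinMap")) {
    dm <- chromatinDomains(x)
    if (!length(dm)) dm <- chromatinDomains(mergeDomains(x))
    dm
  } else x
}

#' Clip chromatin domains to a set of regions
#'
#' Restricts domains to the analysis universe (e.g. the IH bands). A
#' domain belongs to a region when its overlap is at least
#' \code{minOverlap} bp; straddling domains are reported with clipped
#' coordinates and a reference to the parent domain, so membership counts
#' use whole domains while bp accounting stays length-exact.
#'
#' @param domains a [ChromatinMap-class] with merged domains, or a
#'   domain-level \code{GRanges} with a \code{state} column.
#' @param regions [GenomicRanges::GRanges] of regions with a \code{name}
#'   column (see [readRegions()]).
#' @param minOverlap minimum overlap (bp) for membership; default 1.
#' @return \code{GRanges} of clipped segments with columns \code{state},
#'   \code{region} (region name), \code{parent} (index into the domain
#'   set), \code{parentStart}, \code{parentEnd}.
#' @export
clipToRegions <- function(domains, regions, minOverlap = 1) {
  dm <- .domainsOf(domains)
  missing <- setdiff(as.character(unique(seqnames(regions))),
                     as.character(unique(seqnames(dm))))
  if (length(dm) && length(missing))
    stop("region chromosome(s) absent from the map: ",
         paste(missing, collapse = ", "))
  ht <- findOverlaps(dm, regions, minoverlap = minOverlap,
                     ignore.strand = TRUE)
  d <- dm[queryHits(ht)]
  r <- regions[subjectHits(ht)]
  clipped <- pintersect(d, r, ignore.strand = TRUE)
  out <- GRanges(seqnames(clipped), ranges(clipped), seqinfo = seqinfo(dm))
  out$state <- d$state
  out$region <- if (!is.null(r$name)) r$name else as.character(subjectHits(ht))
  out$parent <- queryHits(ht)
  out$parentStart <- start(d)
  out$parentEnd <- end(d)
  out
}

#' Per-state composition of a region set
#'
#' Fraction of the combined region span (or of its assigned part)
#' occupied by each chromatin state. Composition is computed over clipped
#' segment lengths by default, so straddling domains contribute only
#' their in-region bp; set \code{clipped = FALSE} to credit whole
#' straddling domains instead.
#'
#' @param domains a [ChromatinMap-class] with merged domains, or a
#'   domain-level \code{GRanges} with \code{state}.
#' @param regions region \code{GRanges}; \code{NULL} for genome-wide
#'   composition over the map's declared span.
#' @param includeGaps report the \code{gap} share and normalize fractions
#'   over the full span (all five labels sum to 1); with \code{FALSE}
#'   fractions are over the four assigned states only.
#' @param clipped use clipped segment lengths (default) or whole parent
#'   domain lengths for straddlers (gap accounting then unavailable).
#' @param minOverlap membership threshold passed to [clipToRegions()].
#' @return \code{data.frame} with columns \code{state}, \code{bp},
#'   \code{fraction}.
#' @export
stateComposition <- function(domains, regions = NULL, includeGaps = FALSE,
                             clipped = TRUE, minOverlap = 1) {
  dm <- .domainsOf(domains)
  if (is.null(regions)) {
    span <- if (is(domains, "ChromatinMap"))
      sum(as.numeric(chromLengths(domains)))
    else sum(as.numeric(width(dm)))
    bp <- tapply(as.numeric(width(dm)), dm$state, sum, default = 0)
  } else {
    if (!length(regions)) stop("empty region set")
    span <- sum(as.numeric(width(regions)))
    seg <- clipToRegions(dm, regions, minOverlap = minOverlap)
    len <- if (clipped) as.numeric(width(seg))
           else seg$parentEnd - seg$parentStart + 1
    bp <- tapply(len, seg$state, sum, default = 0)
  }
  bp <- setNames(as.numeric(bp[chromatinStates()]), chromatinStates())
  bp[is.na(bp)] <- 0
  if (includeGaps) {
    if (!clipped)
      stop("gap accounting requires clipped = TRUE")
    bp <- c(bp, gap = span - sum(bp))
    frac <- bp / span
  } else {
    frac <- if (sum(bp) > 0) bp / sum(bp) else bp
  }
  data.frame(state = names(bp), bp = unname(bp),
             fraction = unname(frac), stringsAsFactors = FALSE)
}
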