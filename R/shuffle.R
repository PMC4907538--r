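# The domain/spacer index-shuffle permutation test. For one chromatin
# type on one chromosome the map is decomposed into the ordered arrays of
# domain lengths An and spacer lengths Sn (N+1 of them, including the
# stretches from the chromosome start to the first domain and from the
# last domain to the chromosome end). Each Monte-Carlo iteration permutes
# the two index arrays independently and lays the chromosome out as
# S A S A ... S, which preserves both length multisets and the chromosome
# length exactly while randomizing domain positions; the track is never
# shuffled.

#' Decompose domains of one state on one chromosome into an Arrangement
#'
#' @param domains sorted, non-overlapping \code{GRanges} (or
#'   \code{IRanges}) of one chromatin type on a single chromosome.
#' @param chromLength chromosome length (bp); defaults to the declared
#'   seqlength.
#' @param chrom chromosome name (required for \code{IRanges} input).
#' @return an [Arrangement-class]; \code{layoutArrangement(arr)} with
#'   identity orders reproduces the input intervals exactly.
#' @examples
#' gr <- GenomicRanges::GRanges("2L", IRanges::IRanges(c(11, 51), c(20, 70)))
#' arr <- decomposeArrangement(gr, chromLength = 100)
#' domainLengths(arr); spacerLengths(arr)
#' @export
decomposeArrangement <- function(domains, chromLength = NULL,
                                 chrom = NULL) {
  if (is(domains, "GRanges")) {
    chroms <- unique(as.character(seqnames(domains)))
    if (length(chroms) > 1)
      stop("decomposeArrangement works on a single chromosome")
    if (is.null(chrom))
      chrom <- if (length(chroms)) chroms else "chr"
    if (is.null(chromLength)) {
      chromLength <- seqlengths(domains)[chrom]
      if (is.na(chromLength))
        stop("chromLength missing and not declared in seqlengths")
    }
    ir <- ranges(domains)
  } else {
    ir <- domains
    if (is.null(chrom)) chrom <- "chr"
    if (is.null(chromLength)) stop("chromLength required")
  }
  ir <- sort(ir)
  chromLength <- as.numeric(chromLength)
  s0 <- start(ir) - 1  # 0-based starts
  e0 <- end(ir)        # half-open ends
  n <- length(ir)
  if (n && (s0[1] < 0 || e0[n] > chromLength))
    stop("domain outside chromosome bounds")
  if (n > 1 && any(s0[-1] < e0[-n]))
    stop("domains must be non-overlapping")
  A <- as.numeric(e0 - s0)
  S <- if (n) c(s0[1], s0[-1] - e0[-n], chromLength - e0[n])
       else chromLength
  new("Arrangement", chrom = chrom, chromLength = chromLength,
      domainLengths = A, spacerLengths = as.numeric(S))
}

#' Lay out an Arrangement under given index orders
#'
#' Places the chromosome as S A S A ... S using the supplied
#' permutations of the domain and spacer index arrays. With identity
#' orders this inverts [decomposeArrangement()].
#'
#' @param arr an [Arrangement-class].
#' @param orderA,orderS permutations of \code{seq_len(N)} and
#'   \code{seq_len(N + 1)}; identity by default.
#' @return \code{GRanges} of the laid-out domains (1-based), sorted.
#' @export
layoutArrangement <- function(arr, orderA = seq_along(domainLengths(arr)),
                              orderS = seq_along(spacerLengths(arr))) {
  A <- domainLengths(arr)[orderA]
  S <- spacerLengths(arr)[orderS]
  n <- length(A)
  if (length(S) != n + 1) stop("invalid index orders")
  if (!n)
    return(GRanges(seqinfo = Seqinfo(arr@chrom, arr@chromLength)))
  s0 <- cumsum(S[seq_len(n)]) + c(0, cumsum(A))[seq_len(n)]
  GRanges(arr@chrom, IRanges(start = s0 + 1, end = s0 + A),
          seqinfo = Seqinfo(arr@chrom, arr@chromLength))
}

#' Randomly shuffle an Arrangement
#'
#' Permutes the domain and spacer index arrays independently and
#' uniformly (domain i is not kept paired with spacer i) and lays the
#' result out. Both length multisets and the chromosome length are
#' conserved exactly.
#'
#' @param arr an [Arrangement-class].
#' @return \code{GRanges} of the shuffled domain positions.
#' @export
shuffleArrangement <- function(arr) {
  n <- length(domainLengths(arr))
  layoutArrangement(arr, orderA = sample.int(n),
                    orderS = sample.int(n + 1))
}

# merged track intervals on one chromosome, clipped to [0, L), as
# 0-based half-open start/end vectors for the C++ kernel
.trackBed <- function(track, chrom, chromLength) {
  tr <- track[as.character(seqnames(track)) == chrom]
  tr <- reduce(granges(tr), ignore.strand = TRUE)
  s0 <- pmax(start(tr) - 1, 0)
  e0 <- pmin(end(tr), chromLength)
  keep <- e0 > s0
  list(ts = as.numeric(s0[keep]), te = as.numeric(e0[keep]))
}

.observedStat <- function(domains, track, statistic) {
  if (statistic == "length") overlapLength(domains, track)
  else sum(countOverlaps(granges(domains),
                         reduce(granges(track), ignore.strand = TRUE),
                         ignore.strand = TRUE) > 0)
}

.mkShuffleResult <- function(observed, nullSample, M, statistic, chrom) {
  nm <- mean(nullSample)
  ns <- sd(nullSample)
  if (M == 1) ns <- 0
  countGE <- sum(nullSample >= observed)
  countLE <- sum(nullSample <= observed)
  pE <- countGE / M
  pD <- countLE / M
  degenerate <- ns == 0
  method <- "empirical"
  if (!degenerate && (pE %in% c(0, 1) || pD %in% c(0, 1))) {
    # an empirical p of exactly 0 or 1 carries no resolution; replace the
    # saturated value(s) with the Gaussian tail on the null moments
    method <- "normal_approx"
    if (pE %in% c(0, 1))
      pE <- pnorm(observed, mean = nm, sd = ns, lower.tail = FALSE)
    if (pD %in% c(0, 1))
      pD <- pnorm(observed, mean = nm, sd = ns, lower.tail = TRUE)
  }
  new("ShuffleResult", chrom = chrom, statistic = statistic,
      observed = as.numeric(observed), nullMean = nm, nullSd = ns,
      M = as.numeric(M), countGE = as.numeric(countGE),
      countLE = as.numeric(countLE),
      pEnrich = pE, pDeplete = pD,
      pEnrichAdd1 = (countGE + 1) / (M + 1),
      pDepleteAdd1 = (countLE + 1) / (M + 1),
      method = method, degenerate = degenerate)
}

#' Domain-shuffle permutation test on one chromosome
#'
#' Tests whether the overlap between the domains of one chromatin type
#' and a fixed annotation track is larger (enrichment) or smaller
#' (depletion) than expected when the domain/spacer arrangement is
#' randomly re-ordered along the chromosome. The statistic is the total
#' overlap length in bp (default) or the number of overlapping domains.
#' Ties count as extreme on both sides. When an empirical p of exactly 0
#' or 1 is obtained and the null is non-degenerate, the Gaussian tail at
#' the null sample moments is reported instead
#' (\code{method = "normal_approx"}).
#'
#' Randomness comes from R's RNG: call \code{set.seed()} (or pass
#' \code{seed}) for reproducible runs.
#'
#' @param domains \code{GRanges} of one chromatin type on one chromosome.
#' @param track annotation track \code{GRanges}; never shuffled.
#' @param chromLength chromosome length (bp); defaults to the declared
#'   seqlength.
#' @param M number of shuffle iterations (default 1e4).
#' @param statistic \code{"length"} or \code{"count"}.
#' @param seed optional integer seed applied via \code{set.seed()}.
#' @return a [ShuffleResult-class].
#' @examples
#' set.seed(1)
#' dom <- GenomicRanges::GRanges("2L",
#'   IRanges::IRanges(c(1001, 5001), width = 400),
#'   seqlengths = c(`2L` = 10000))
#' trk <- GenomicRanges::GRanges("2L",
#'   IRanges::IRanges(c(900, 4800), width = 700))
#' permutationTest(dom, trk, M = 1000)
#' @export
permutationTest <- function(domains, track, chromLength = NULL,
                            M = 10000, statistic = c("length", "count"),
                            seed = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  arr <- decomposeArrangement(domains, chromLength = chromLength)
  if (!length(domainLengths(arr))) stop("no domains on the chromosome")
  tb <- .trackBed(track, arr@chrom, arr@chromLength)
  nullSample <- cpp_shuffle_null(domainLengths(arr), spacerLengths(arr),
                                 tb$ts, tb$te, as.integer(M),
                                 statistic == "count")
  observed <- .observedStat(domains, track, statistic)
  .mkShuffleResult(observed, nullSample, M, statistic, arr@chrom)
}

#' Genome-wide domain-shuffle permutation test
#'
#' Runs the shuffle simultaneously on all chromosomes: each iteration
#' re-arranges every chromosome independently and the statistic is the
#' sum of per-chromosome overlaps, giving a single whole-genome pair of
#' enrichment/depletion p-values. On a single-chromosome genome this is
#' identical to [permutationTest()] under the same seed.
#'
#' @param domains \code{GRanges} of one chromatin type, any number of
#'   chromosomes.
#' @param track annotation track \code{GRanges}.
#' @param chromLengths named vector of chromosome lengths; defaults to
#'   the declared seqlengths.
#' @param M,statistic,seed as in [permutationTest()].
#' @return a [ShuffleResult-class] with \code{chrom = "genome"}.
#' @export
genomeWideTest <- function(domains, track, chromLengths = NULL,
                           M = 10000, statistic = c("length", "count"),
                           seed = NULL) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(as.character(seqnames(domains)))
  if (!length(chroms)) stop("no domains supplied")
  if (is.null(chromLengths)) {
    chromLengths <- seqlengths(domains)[chroms]
    if (any(is.na(chromLengths)))
      stop("chromLengths missing and not declared in seqlengths")
  }
  nullTotal <- numeric(M)
  observed <- 0
  for (ch in chroms) {
    dch <- domains[as.character(seqnames(domains)) == ch]
    arr <- decomposeArrangement(dch, chromLength = chromLengths[[ch]],
                                chrom = ch)
    tb <- .trackBed(track, ch, arr@chromLength)
    nullTotal <- nullTotal +
      cpp_shuffle_null(domainLengths(arr), spacerLengths(arr),
                       tb$ts, tb$te, as.integer(M),
                       statistic == "count")
    tch <- track[as.character(seqnames(track)) == ch]
    observed <- observed + .observedStat(dch, tch, statistic)
  }
  .mkShuffleResult(observed, nullTotal, M, statistic, "genome")
}

#' Gaussian tail p-value against a Monte-Carlo null sample
#'
#' Upper (enrichment) or lower (depletion) normal tail at
#' \code{z = (observed - mean) / sd}, using the sample moments of the
#' null. Used when the empirical p saturates at 0 or 1. A degenerate
#' null (sd = 0) is flagged with a warning and the empirical tie-counting
#' p is returned instead.
#'
#' @param observed observed statistic.
#' @param nullSample numeric vector of null draws.
#' @param side \code{"enrich"} (upper tail) or \code{"deplete"}.
#' @return p-value in \[0, 1\].
#' @export
normalTailP <- function(observed, nullSample,
                        side = c("enrich", "deplete")) {
  side <- match.arg(side)
  m <- mean(nullSample)
  s <- sd(nullSample)
  if (is.na(s) || s == 0) {
    warning("degenerate null (sd = 0); returning empirical p")
    return(if (side == "enrich") mean(nullSample >= observed)
           else mean(nullSample <= observed))
  }
  pnorm(observed, mean = m, sd = s, lower.tail = side == "deplete")
}

#' Settings bundle for the shuffle test
#'
#' Convenience constructor for the shuffle settings consumed by
#' [runPipeline()].
#'
#' @param M shuffle iterations (default 1e4; raise towards 1e6 for
#'   publication-grade tail resolution).
#' @param seed integer seed recorded in outputs.
#' @param statistic \code{"length"} or \code{"count"}.
#' @return a named list with class \code{"shuffleConfig"}.
#' @export
shuffleConfig <- function(M = 10000, seed = 1L,
                          statistic = c("length", "count")) {
  stopifnot(M >= 1)
  structure(list(M = M, seed = as.integer(seed),
                 statistic = match.arg(statistic)),
            class = "shuffleConfig")
}
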