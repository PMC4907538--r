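# Replication-timing profiles by chromatin class. Timing scores are
# signed: positive = early, negative = late replication.

#' Assign replication probes to chromatin classes
#'
#' A probe is assigned to the chromatin class covering at least
#' \code{minFrac} of its length (the boundary is inclusive: exactly 50%
#' qualifies at the default). Probes not reaching the threshold for any
#' class stay unassigned (\code{NA}). With \code{minFrac <= 0.5} two
#' classes can tie at the threshold; the one covering more bp wins, ties
#' broken by state order.
#'
#' @param probes \code{GRanges} of probes (see [readProbes()]).
#' @param map a [ChromatinMap-class] with merged domains, or a domain
#'   \code{GRanges} with \code{state}.
#' @param minFrac minimum covered fraction of the probe length.
#' @return factor of class assignments (levels = [chromatinStates()]),
#'   \code{NA} = unassigned.
#' @export
assignProbeClass <- function(probes, map, minFrac = 0.5) {
  dm <- .domainsOf(map)
  cls <- factor(rep(NA_character_, length(probes)),
                levels = chromatinStates())
  ht <- findOverlaps(probes, dm, ignore.strand = TRUE)
  if (!length(ht)) return(cls)
  ov <- width(pintersect(probes[queryHits(ht)], dm[subjectHits(ht)],
                         ignore.strand = TRUE))
  st <- as.character(dm$state)[subjectHits(ht)]
  # total covered bp per (probe, state): a class split across several
  # domains inside one probe still accumulates
  agg <- rowsum(as.numeric(ov),
                group = paste(queryHits(ht), st, sep = "\r"))
  key <- rownames(agg)
  probeIdx <- as.integer(sub("\r.*", "", key))
  stateOf <- sub(".*\r", "", key)
  w <- as.numeric(width(probes))[probeIdx]
  frac <- agg[, 1] / w
  ord <- order(probeIdx, -frac,
               match(stateOf, chromatinStates()))
  first <- !duplicated(probeIdx[ord])
  win <- ord[first]
  ok <- frac[win] >= minFrac
  cls[probeIdx[win][ok]] <- stateOf[win][ok]
  cls
}

#' Binned timing-score densities per chromatin class
#'
#' Histograms of replication-timing scores in fixed-width bins (0.5 score
#' units by default), normalised to sum to 1 within each class so that
#' classes with very different probe counts are comparable.
#'
#' @param scores numeric timing scores.
#' @param classes class per probe (factor or character; \code{NA}
#'   dropped).
#' @param width bin width in score units.
#' @return \code{data.frame} with \code{class}, \code{binLow},
#'   \code{binMid}, \code{count}, \code{density}; densities sum to 1 per
#'   class.
#' @export
binTimingScores <- function(scores, classes, width = 0.5) {
  stopifnot(length(scores) == length(classes), width > 0)
  keep <- !is.na(classes)
  scores <- scores[keep]; classes <- as.character(classes)[keep]
  if (!length(scores)) stop("no classified probes to bin")
  lo <- floor(min(scores) / width) * width
  hi <- ceiling(max(scores) / width) * width
  if (hi <= lo) hi <- lo + width
  edges <- seq(lo, hi, by = width)
  rows <- lapply(sort(unique(classes)), function(cl) {
    s <- scores[classes == cl]
    h <- hist(s, breaks = edges, plot = FALSE)
    data.frame(class = cl, binLow = edges[-length(edges)],
               binMid = h$mids, count = h$counts,
               density = h$counts / length(s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Border-to-center replication-timing gradient of an IH region
#'
#' Within an IH band, replication typically starts at the early flanks
#' and finishes in the late center: the timing score falls with distance
#' from the nearest region border. For each probe midpoint inside the
#' region the distance to the nearest border is computed
#' (\code{min(mid - start, end - mid)}), and the gradient is quantified
#' as the Spearman rank correlation and the least-squares slope of score
#' versus distance (reported per kb). The statistic is symmetric under
#' coordinate reversal of the region and invariant under translation.
#'
#' @param probes \code{GRanges} with \code{score} (timing).
#' @param region a single region (\code{GRanges} of length 1).
#' @return \code{list} with \code{n}, \code{spearman}, \code{slopePerKb},
#'   \code{slopeSE}, \code{defined} (\code{FALSE} when fewer than 3
#'   probes fall inside the region, in which case the statistics are
#'   \code{NA}), and \code{data} (per-probe distance/score table).
#' @export
borderGradient <- function(probes, region) {
  stopifnot(length(region) == 1)
  p <- probes[as.character(seqnames(probes)) ==
                as.character(seqnames(region))]
  mid <- (start(p) + end(p)) / 2
  rs <- start(region) - 1; re <- end(region)  # 0-based borders
  inside <- mid > rs & mid < re
  p <- p[inside]; mid <- mid[inside]
  dist <- pmin(mid - rs, re - mid)
  df <- data.frame(distance = dist, score = p$score)
  if (nrow(df) < 3)
    return(list(n = nrow(df), spearman = NA_real_,
                slopePerKb = NA_real_, slopeSE = NA_real_,
                defined = FALSE, data = df))
  rho <- if (sd(df$score) == 0 || sd(df$distance) == 0) 0
         else suppressWarnings(cor(df$score, df$distance,
                                   method = "spearman"))
  fit <- lm(score ~ I(distance / 1000), data = df)
  # a perfect (noise-free) fit triggers a harmless zero-variance note
  se <- suppressWarnings(sqrt(diag(vcov(fit)))[2])
  list(n = nrow(df), spearman = rho,
       slopePerKb = unname(coef(fit)[2]),
       slopeSE = unname(se), defined = TRUE, data = df)
}
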