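# Hand-built toy maps and small generators shared across tests.
# Coordinates in these helpers are 0-based half-open (BED style), as in
# the on-disk formats; builders convert to GRanges internally.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# one fragment row
frag <- function(chrom, start, end, state) {
  data.frame(chrom = chrom, start = start, end = end, state = state,
             stringsAsFactors = FALSE)
}

# n abutting 200-bp fragments of one state starting at `start`
tileFrags <- function(chrom, start, n, state) {
  s <- start + 200 * (seq_len(n) - 1)
  data.frame(chrom = chrom, start = s, end = s + 200, state = state,
             stringsAsFactors = FALSE)
}

# build a ChromatinMap from a data.frame of 0-based rows
toyMap <- function(rows, chromLengths) {
  gr <- GRanges(rows$chrom, IRanges(rows$start + 1, rows$end))
  gr$state <- rows$state
  ChromatinMap(gr, chromLengths = chromLengths)
}

# GRanges from 0-based triples
gr0 <- function(chrom, start, end, ...) {
  g <- GRanges(chrom, IRanges(start + 1, end))
  extra <- list(...)
  for (nm in names(extra)) mcols(g)[[nm]] <- extra[[nm]]
  g
}

# named region
region0 <- function(chrom, start, end, name = "R1") {
  g <- gr0(chrom, start, end)
  g$name <- name
  g
}

# small spec for fast generator tests: one 400 kb chromosome, one IH
smallSpec <- function(...) {
  mapSpec(chromLengths = c(chrA = 4e5), ihCount = 1,
          ihLenRange = c(8e4, 1.2e5), ...)
}

# exhaustive layouts of a 2-domain / 3-spacer arrangement and their
# overlap statistic against a fixed track; the independent oracle for
# the Monte-Carlo null
enumerateNull <- function(arr, track) {
  perms2 <- list(1:2, 2:1)
  perms3 <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                 c(3,1,2), c(3,2,1))
  stats <- numeric(0)
  for (pa in perms2) for (ps in perms3) {
    lay <- layoutArrangement(arr, orderA = pa, orderS = ps)
    stats <- c(stats, overlapLength(lay, track))
  }
  stats
}

# per-base brute-force overlap on a toy chromosome (oracle for
# overlapLength): counts bases covered by both sets
bruteOverlap <- function(a, b, L) {
  ca <- cb <- logical(L)
  for (i in seq_along(a)) ca[start(a)[i]:end(a)[i]] <- TRUE
  for (i in seq_along(b)) cb[start(b)[i]:end(b)[i]] <- TRUE
  sum(ca & cb)
}
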