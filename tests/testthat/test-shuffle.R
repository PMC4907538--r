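test_that("arrangement decomposition and layout are exact inverses", {
  gr <- gr0("c", c(10, 50), c(20, 70))
  arr <- decomposeArrangement(gr, chromLength = 100)
  expect_equal(domainLengths(arr), c(10, 20))
  expect_equal(spacerLengths(arr), c(10, 30, 30))
  # empty chromosome
  arr0 <- decomposeArrangement(GRanges(), chromLength = 500,
                               chrom = "c")
  expect_equal(length(domainLengths(arr0)), 0)
  expect_equal(spacerLengths(arr0), 500)
  # identity layout reproduces the input
  expect_equal(ranges(layoutArrangement(arr)), ranges(gr))
  # round-trip identity on random maps
  set.seed(3)
  for (rep in 1:25) {
    # build valid sorted non-overlapping domains from gap/length draws
    n <- sample(1:15, 1)
    gaps <- sample(0:200, n + 1, TRUE)
    lens <- sample(1:150, n, TRUE)
    s <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(lens))[seq_len(n)]
    g <- gr0("c", s, s + lens)
    a <- decomposeArrangement(g, chromLength = 5000)
    expect_equal(sum(domainLengths(a)) + sum(spacerLengths(a)), 5000)
    expect_equal(ranges(layoutArrangement(a)), ranges(g))
  }
  # out-of-bounds domains are rejected
  expect_error(decomposeArrangement(gr0("c", 90, 120),
                                    chromLength = 100), "bounds")
})

test_that("shuffling conserves length multisets and explores layouts uniformly", {
  arr <- decomposeArrangement(gr0("c", c(100, 700), c(400, 1000)),
                              chromLength = 3000)
  set.seed(9)
  for (rep in 1:50) {
    sh <- shuffleArrangement(arr)
    expect_equal(sort(width(sh)), sort(domainLengths(arr)))
    a2 <- decomposeArrangement(sh, chromLength = 3000)
    expect_equal(sort(spacerLengths(a2)), sort(spacerLengths(arr)))
  }
  # N=2 with 3 distinct spacers: 2! * 3! = 12 equally likely layouts
  arrD <- new("Arrangement", chrom = "c", chromLength = 9000,
              domainLengths = c(400, 1000),
              spacerLengths = c(600, 2000, 5000))
  set.seed(21)
  draws <- replicate(6000, {
    sh <- shuffleArrangement(arrD)
    paste(start(sh), collapse = ",")
  })
  tab <- table(draws)
  expect_equal(length(tab), 12)
  # chi-square uniformity check, generous threshold
  chi <- sum((tab - 500)^2 / 500)
  expect_lt(chi, qchisq(0.999, df = 11))
})

test_that("Monte-Carlo null agrees with an independent R shuffle path", {
  # the C++ kernel and an all-R shuffle must target one distribution
  arr <- decomposeArrangement(
    gr0("c", c(500, 2000, 4000, 7000), c(900, 2600, 5000, 7400)),
    chromLength = 10000)
  track <- gr0("c", c(0, 3000, 8000), c(1500, 3500, 9000))
  ts <- c(0, 3000, 8000); te <- c(1500, 3500, 9000)
  A <- domainLengths(arr); S <- spacerLengths(arr); n <- length(A)
  # vectorized bed-coordinate overlap of one random layout
  refOnce <- function() {
    a <- A[sample.int(n)]; s <- S[sample.int(n + 1)]
    s0 <- cumsum(s[seq_len(n)]) + c(0, cumsum(a))[seq_len(n)]
    e0 <- s0 + a
    sum(pmax(0, outer(e0, te, pmin) - outer(s0, ts, pmax)))
  }
  set.seed(4)
  refStats <- replicate(4000, refOnce())
  dom <- layoutArrangement(arr)
  set.seed(4)
  resC <- permutationTest(dom, track, chromLength = 10000, M = 4000)
  expect_lt(abs(nullMoments(resC)["mean"] - mean(refStats)) /
              sd(refStats), 0.1)
  # compare full distributions via two-sample KS distance
  set.seed(4)
  nullC <- ihscape:::cpp_shuffle_null(A, S, ts, te, 4000L, FALSE)
  D <- suppressWarnings(ks.test(nullC, refStats)$statistic)
  expect_lt(D, 0.05)
  # the GRanges layout path agrees with the vector arithmetic exactly,
  # order by order
  set.seed(11)
  for (i in 1:20) {
    oa <- sample.int(n); os <- sample.int(n + 1)
    lay <- layoutArrangement(arr, orderA = oa, orderS = os)
    a <- A[oa]; s <- S[os]
    s0 <- cumsum(s[seq_len(n)]) + c(0, cumsum(a))[seq_len(n)]
    e0 <- s0 + a
    manual <- sum(pmax(0, outer(e0, te, pmin) - outer(s0, ts, pmax)))
    expect_equal(overlapLength(lay, track), manual)
  }
})

test_that("degenerate and empty tracks give the forced p-values", {
  dom <- gr0("c", c(100, 600), c(300, 1000))
  # track = entire chromosome: null degenerate at the total domain bp
  full <- gr0("c", 0, 2000)
  res <- permutationTest(dom, full, chromLength = 2000, M = 200)
  expect_equal(res@observed, 600)
  expect_equal(nullMoments(res)[["sd"]], 0)
  expect_true(res@degenerate)
  expect_equal(pEnrich(res), 1)  # ties count as extreme
  expect_equal(pDeplete(res), 1)
  expect_identical(res@method, "empirical")
  # empty track: observed 0 equals every null draw
  res0 <- permutationTest(dom, GRanges(), chromLength = 2000, M = 200)
  expect_equal(res0@observed, 0)
  expect_equal(pDeplete(res0), 1)
  # tie counting: countGE + countLE >= M always
  expect_gte(res0@countGE + res0@countLE, res0@M)
})

test_that("normal tail p-values match an independent erfc evaluation", {
  set.seed(2)
  null <- rnorm(5000, mean = 100, sd = 12)
  m <- mean(null); s <- sd(null)
  expect_equal(normalTailP(m, null, "enrich"), 0.5)
  expect_equal(normalTailP(m + 1.959964 * s, null, "enrich"), 0.025,
               tolerance = 1e-6)
  # agreement with the complementary error function to 1e-12
  for (obs in c(80, 95, 100, 110, 130)) {
    z <- (obs - m) / s
    expect_equal(normalTailP(obs, null, "enrich"),
                 0.5 * pracma::erfc(z / sqrt(2)), tolerance = 1e-12)
    expect_equal(normalTailP(obs, null, "deplete"),
                 0.5 * pracma::erfc(-z / sqrt(2)), tolerance = 1e-12)
  }
  # degenerate null flagged, empirical p returned
  expect_warning(p <- normalTailP(5, rep(5, 10), "enrich"),
                 "degenerate")
  expect_equal(p, 1)
})

test_that("genome-wide test reduces to the single-chromosome test", {
  dom <- GRanges("c", IRanges(c(1001, 5001), width = 600),
                 seqlengths = c(c = 20000))
  trk <- gr0("c", c(800, 6000), c(2000, 7000))
  r1 <- permutationTest(dom, trk, M = 500, seed = 42)
  r2 <- genomeWideTest(dom, trk, M = 500, seed = 42)
  expect_equal(r1@observed, r2@observed)
  expect_equal(nullMoments(r1), nullMoments(r2))
  expect_equal(pEnrich(r1), pEnrich(r2))
  # two chromosomes: observed adds up
  dom2 <- GRanges(c("a", "b"), IRanges(c(1001, 2001), width = 500),
                  seqlengths = c(a = 10000, b = 10000))
  trk2 <- GRanges(c("a", "b"), IRanges(c(1101, 2101), width = 200))
  rg <- genomeWideTest(dom2, trk2, M = 200, seed = 1)
  expect_equal(rg@observed, 400)
  expect_identical(rg@chrom, "genome")
})

test_that("planted enrichment drives p to zero and add-one estimators never vanish", {
  set.seed(8)
  g <- genMap(smallSpec())
  map <- mergeDomains(fillGaps(g$map))
  dm <- chromatinDomains(map)
  q <- dm[dm$state == "aquamarine"]
  trk <- genTrack(map, trackSpec(fold = 8, baseDensity = 0.03))
  res <- genomeWideTest(q, trk, chromLengths = chromLengths(map),
                        M = 2000)
  expect_lt(pEnrich(res), 0.01)
  expect_gt(res@pEnrichAdd1, 0)
  expect_gt(res@pDepleteAdd1, 0)
})
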