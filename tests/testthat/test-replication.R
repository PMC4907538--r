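test_that("probe class assignment honours the 50% coverage rule", {
  rows <- rbind(tileFrags("c", 0, 5, "malachite"),   # [0, 1000)
                tileFrags("c", 1000, 5, "ruby"))     # [1000, 2000)
  m <- mergeDomains(toyMap(rows, c(c = 2400)))
  probes <- gr0("c", c(100, 900, 1900, 2100), c(200, 1100, 2100, 2300))
  cls <- assignProbeClass(probes, m)
  expect_identical(as.character(cls[1]), "malachite")  # fully inside
  # exactly 50/50 malachite/ruby: threshold is inclusive; the tie is
  # broken by state order
  expect_identical(as.character(cls[2]), "malachite")
  # half ruby, half past the map's domains: 50% ruby qualifies
  expect_identical(as.character(cls[3]), "ruby")
  # fully outside any domain: unassigned
  expect_true(is.na(cls[4]))
  # stricter threshold drops the 50/50 probe
  cls60 <- assignProbeClass(probes, m, minFrac = 0.6)
  expect_true(is.na(cls60[2]))
})

test_that("timing histograms are normalized per class", {
  scores <- c(rep(1.2, 5), c(-0.3, -0.8, 0.1, 2.2))
  classes <- c(rep("ruby", 5), rep("aquamarine", 4))
  h <- binTimingScores(scores, classes, width = 0.5)
  for (cl in c("ruby", "aquamarine"))
    expect_equal(sum(h$density[h$class == cl]), 1, tolerance = 1e-12)
  # all scores identical: single occupied bin with density 1
  h1 <- binTimingScores(rep(0.7, 10), rep("ruby", 10))
  expect_equal(sum(h1$count > 0), 1)
  expect_equal(max(h1$density), 1)
  expect_error(binTimingScores(numeric(0), character(0)), "no classified")
})

test_that("border gradient is symmetric, translation-invariant and flags tiny input", {
  reg <- region0("c", 10000, 50000)
  set.seed(6)
  pos <- seq(10500, 49500, by = 500)
  # width-49 probes so the midpoint sits exactly on p and the mirror
  # reflection is coordinate-exact
  mkProbes <- function(p, s) gr0("c", p - 25, p + 24, score = s)
  # constant score: zero correlation and slope
  g0 <- borderGradient(mkProbes(pos, rep(1.5, length(pos))), reg)
  expect_equal(g0$spearman, 0)
  expect_equal(g0$slopePerKb, 0, tolerance = 1e-12)
  # planted decreasing gradient
  d <- pmin(pos - 10000, 50000 - pos)
  sc <- 2 - 0.05 * d / 1000 + rnorm(length(pos), 0, 0.1)
  g1 <- borderGradient(mkProbes(pos, sc), reg)
  expect_lt(g1$spearman, -0.8)
  expect_lt(abs(g1$slopePerKb - (-0.05)), 3 * g1$slopeSE)
  # translation invariance
  shift <- 123456
  g2 <- borderGradient(mkProbes(pos + shift, sc),
                       region0("c", 10000 + shift, 50000 + shift))
  expect_equal(g2$slopePerKb, g1$slopePerKb)
  expect_equal(g2$spearman, g1$spearman)
  # mirror symmetry: reflect probes around the region midpoint
  mirrored <- 60000 - pos
  g3 <- borderGradient(mkProbes(mirrored, sc), reg)
  expect_equal(g3$slopePerKb, g1$slopePerKb, tolerance = 1e-9)
  expect_equal(g3$spearman, g1$spearman, tolerance = 1e-9)
  # fewer than 3 probes: undefined, flagged
  gf <- borderGradient(mkProbes(pos[1:2], sc[1:2]), reg)
  expect_false(gf$defined)
  expect_true(is.na(gf$slopePerKb))
})

test_that("noise-free generated gradients are perfectly monotone", {
  set.seed(19)
  g <- genMap(smallSpec())
  map <- mergeDomains(fillGaps(g$map))
  pr <- genProbes(map, g$ihRegions, slopePerKb = 0.05, noiseSd = 0)
  res <- borderGradient(pr, g$ihRegions[1])
  expect_equal(res$spearman, -1)
  expect_equal(res$slopePerKb, -0.05, tolerance = 1e-9)
  # zero slope, zero noise: flat profile
  pr0 <- genProbes(map, g$ihRegions, slopePerKb = 0, noiseSd = 0)
  resFlat <- borderGradient(pr0, g$ihRegions[1])
  expect_equal(resFlat$spearman, 0)
  expect_equal(resFlat$slopePerKb, 0, tolerance = 1e-12)
})

test_that("border malachite replicates earlier than internal malachite under a planted gradient", {
  set.seed(23)
  g <- genMap(smallSpec())
  map <- mergeDomains(fillGaps(g$map))
  pr <- genProbes(map, g$ihRegions, slopePerKb = 0.03, noiseSd = 0.2)
  lab <- classifyMalachite(map, g$ihRegions)
  ht <- findOverlaps(pr, lab, select = "first")
  inMal <- !is.na(ht)
  labels <- lab$label[ht[inMal]]
  scores <- pr$score[inMal]
  expect_gt(mean(scores[labels == "border"]),
            mean(scores[labels == "internal"]))
})
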