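test_that("generators are deterministic given the seed", {
  sp <- smallSpec()
  g1 <- genMap(sp, seed = 99)
  g2 <- genMap(sp, seed = 99)
  expect_identical(stateFragments(g1$map), stateFragments(g2$map))
  expect_identical(g1$ihRegions, g2$ihRegions)
  map <- mergeDomains(fillGaps(g1$map))
  t1 <- genTrack(map, trackSpec(fold = 3), seed = 5)
  t2 <- genTrack(map, trackSpec(fold = 3), seed = 5)
  expect_identical(ranges(t1), ranges(t2))
  p1 <- genPeaks(map, seed = 5)
  p2 <- genPeaks(map, seed = 5)
  expect_identical(p1$score, p2$score)
  r1 <- genProbes(map, g1$ihRegions, seed = 5)
  r2 <- genProbes(map, g1$ihRegions, seed = 5)
  expect_identical(r1$score, r2$score)
})

test_that("single-state specs give single-state maps without contacts", {
  sp <- mapSpec(chromLengths = c(chrA = 2e5),
                stateFreq = c(aquamarine = 0, lazurite = 0,
                              malachite = 0, ruby = 1),
                ihStateFreq = c(aquamarine = 0, lazurite = 0,
                                malachite = 0, ruby = 1),
                ihCount = 0, gapRate = 0)
  g <- genMap(sp, seed = 1)
  map <- mergeDomains(fillGaps(g$map))
  st <- unique(as.character(chromatinDomains(map)$state))
  expect_identical(st, "ruby")
  expect_equal(attr(contactMatrix(map), "total"), 0)
})

test_that("generated maps satisfy fragment invariants and round-trip through readers", {
  g <- genMap(smallSpec(), seed = 12)
  fr <- stateFragments(g$map)
  # non-gap fragments are exactly 200 bp; total tiling holds
  expect_true(all(width(fr[fr$state != "gap"]) == 200))
  expect_equal(sum(width(fr)), 4e5)
  # written files re-read losslessly
  dir <- tempfile(); dir.create(dir)
  paths <- writeFixtures(dir, seed = 12, spec = smallSpec())
  m2 <- readStateMap(paths$map, chromSizes = paths$chromSizes)
  expect_identical(granges(stateFragments(m2)),
                   granges(stateFragments(g$map)))
  expect_identical(as.character(stateFragments(m2)$state),
                   as.character(stateFragments(g$map)$state))
  reg <- readRegions(paths$regions)
  expect_equal(ranges(reg), ranges(g$ihRegions))
  expect_identical(reg$name, g$ihRegions$name)
  pr <- readProbes(paths$probes)
  expect_gt(length(pr), 100)
  expect_true(is.numeric(pr$score))
})

test_that("domain lengths follow the configured log-normal", {
  sp <- mapSpec(chromLengths = c(chrA = 4e6), ihCount = 0,
                gapRate = 0,
                stateFreq = c(aquamarine = 0.25, lazurite = 0.25,
                              malachite = 0.25, ruby = 0.25))
  g <- genMap(sp, seed = 77)
  lay <- g$truth$layout
  obs <- lay$end[lay$state == "malachite"] -
    lay$start[lay$state == "malachite"]
  expect_gt(length(obs), 300)
  # reference sample from the same discretized distribution
  set.seed(78)
  p <- sp$lenParams$malachite
  ref <- pmax(200, round(rlnorm(5000, p$meanlog, p$sdlog) / 200) * 200)
  ks <- suppressWarnings(ks.test(obs, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("track generator plants the requested density pattern", {
  set.seed(41)
  g <- genMap(smallSpec())
  map <- mergeDomains(fillGaps(g$map))
  dm <- chromatinDomains(map)
  aq <- dm[dm$state == "aquamarine"]
  # fold 0: the target state carries no track at all
  t0 <- genTrack(map, trackSpec(fold = 0, baseDensity = 0.05))
  expect_equal(overlapLength(aq, t0), 0)
  expect_gt(length(t0), 0)
  # fold 4: observed in-state density close to 4 * base
  t4 <- genTrack(map, trackSpec(fold = 4, baseDensity = 0.03))
  dens <- overlapLength(aq, t4) / sum(width(reduce(aq)))
  expect_equal(dens, 0.12, tolerance = 0.15)
  # infeasible coverage rejected
  expect_error(trackSpec(fold = 50, baseDensity = 0.1), "coverage")
})

test_that("peak generator respects per-state rates", {
  set.seed(51)
  g <- genMap(smallSpec())
  map <- mergeDomains(fillGaps(g$map))
  expect_equal(length(genPeaks(map, ratesPerMb = c(
    aquamarine = 0, lazurite = 0, malachite = 0, ruby = 0))), 0)
  pk <- genPeaks(map, ratesPerMb = c(aquamarine = 400, lazurite = 0,
                                     malachite = 0, ruby = 4))
  expect_true(all(pk$score >= 1))
  pd <- peakDensityByReadCount(pk, map)
  byState <- tapply(pd$count, pd$state, sum)
  dm <- chromatinDomains(map)
  bp <- tapply(as.numeric(width(dm)), as.character(dm$state), sum)
  rateAq <- byState[["aquamarine"]] / (bp[["aquamarine"]] / 1e6)
  rateRb <- byState[["ruby"]] / (bp[["ruby"]] / 1e6)
  # two orders of magnitude apart, as planted
  expect_gt(rateAq / max(rateRb, 1), 25)
})
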