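test_that("TSS class assignment follows the half-open convention", {
  rows <- rbind(tileFrags("c", 0, 2, "ruby"),        # [0, 400)
                tileFrags("c", 400, 2, "malachite"), # [400, 800)
                frag("c", 800, 1400, "gap"),
                tileFrags("c", 1400, 1, "aquamarine"))
  m <- mergeDomains(toyMap(rows, c(c = 1600)))
  tss <- gr0("c", c(100, 400, 399, 1000), c(101, 401, 400, 1001))
  tss <- GRanges("c", IRanges(start = c(100, 400, 399, 1000) + 1,
                              width = 1))
  cls <- assignTssClass(tss, m)
  expect_identical(cls[1], "ruby")
  # base 400 is the first base of the malachite span
  expect_identical(cls[2], "malachite")
  # base 399 is the last ruby base
  expect_identical(cls[3], "ruby")
  # TSS in a residual gap is unassigned
  expect_identical(cls[4], "unassigned")
  # TSS beyond chromosome bounds errors
  expect_error(assignTssClass(GRanges("c", IRanges(5000, width = 1)),
                              m), "outside the map")
  # border/internal malachite refinement
  lab <- gr0("c", 400, 800, label = "border")
  cls2 <- assignTssClass(tss, m, malachiteLabels = lab)
  expect_identical(cls2[2], "malachite_border")
})

test_that("expression breadth counts tissues above a strict threshold", {
  m <- rbind(rep(0, 5),
             c(3, 3, 3, 3, 3),     # exactly at threshold: silent
             c(10, 2, 4, 3.01, 0))
  expect_equal(expressionBreadth(m), c(0L, 0L, 3L))
  # monotone non-increasing in the threshold
  set.seed(13)
  mm <- matrix(rlnorm(200, 1, 1.5), 20, 10)
  b3 <- expressionBreadth(mm, threshold = 3)
  b5 <- expressionBreadth(mm, threshold = 5)
  expect_true(all(b5 <= b3))
})

test_that("quartile summaries follow the linear-interpolation convention", {
  expect_equal(unname(expressionQuartiles(rep(7, 10))), rep(7, 5))
  q <- expressionQuartiles(1:8)
  expect_equal(unname(q["q2"]), 4.5)
  # ordering holds for random input
  set.seed(7)
  for (rep in 1:10) {
    q <- expressionQuartiles(rnorm(sample(3:50, 1)))
    expect_true(all(diff(q) >= 0))
  }
  expect_error(expressionQuartiles(numeric(0)), "empty")
})

test_that("planted class-dependent breadth ordering is recovered", {
  set.seed(31)
  g <- genMap(smallSpec())
  map <- mergeDomains(fillGaps(g$map))
  ex <- genExpression(map, nPerClass = 150)
  # transcripts fall in the class they were planted in
  cls <- assignTssClass(ex$se, map)
  expect_true(mean(cls == ex$truth) > 0.99)
  es <- expressionSummary(ex$se, ex$truth)
  med <- setNames(es$medianBreadth, es$class)
  # planted ordering: aquamarine > malachite > ruby
  expect_gt(med["aquamarine"], med["malachite"])
  expect_gt(med["malachite"], med["ruby"])
  # binomial expectation: median breadth ~ 29 * q
  expect_equal(unname(med["aquamarine"]), 29 * 0.9, tolerance = 0.1)
  # degenerate probabilities
  ex0 <- genExpression(map, nPerClass = 30, params = list(
    aquamarine = list(q = 0, meanlog = 1, sdlog = 1, qCell = 0),
    lazurite   = list(q = 1, meanlog = 1, sdlog = 1, qCell = 1),
    malachite  = list(q = 0, meanlog = 1, sdlog = 1, qCell = 0),
    ruby       = list(q = 0, meanlog = 1, sdlog = 1, qCell = 0)))
  b <- expressionBreadth(ex0$se)
  expect_true(all(b[ex0$truth == "aquamarine"] == 0))
  expect_true(all(b[ex0$truth == "lazurite"] == 29))
})

test_that("transcript tables round-trip through the TSV writer", {
  set.seed(17)
  g <- genMap(smallSpec())
  map <- mergeDomains(fillGaps(g$map))
  ex <- genExpression(map, nPerClass = 20)
  tf <- tempfile(fileext = ".tsv")
  writeTranscripts(ex$se, tf)
  se2 <- readTranscripts(tf, manifest = paste0(tf, ".manifest"))
  expect_equal(SummarizedExperiment::assay(se2, "rpkm"),
               SummarizedExperiment::assay(ex$se, "rpkm"),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(start(SummarizedExperiment::rowRanges(se2)),
               start(SummarizedExperiment::rowRanges(ex$se)))
  expect_identical(se2$group, ex$se$group)
})
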