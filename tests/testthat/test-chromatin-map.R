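test_that("state map parsing handles records, legacy labels and gap materialization", {
  tf <- tempfile()
  writeLines(c("2L\t0\t200\truby",
               "2L\t200\t400\tmagenta",     # legacy label for ruby
               "2L\t1000\t1200\tgreen"),    # legacy label for malachite
             tf)
  m <- readStateMap(tf, chromSizes = c(`2L` = 2000))
  fr <- stateFragments(m)
  expect_identical(as.character(fr$state[1]), "ruby")
  expect_identical(as.character(fr$state[2]), "ruby")
  # uncovered [400,1000) and [1200,2000) become explicit gaps
  gaps <- fr[fr$state == "gap"]
  expect_equal(start(gaps) - 1, c(400, 1200))
  expect_equal(end(gaps), c(1000, 2000))
  # total tiling equals the declared chromosome length
  expect_equal(sum(width(fr)), 2000)
  expect_equal(mappedLength(m) + gapLength(m), 2000)
})

test_that("state map parsing rejects malformed and inconsistent input", {
  bad <- tempfile()
  writeLines(c("2L\t0\t200\truby", "2L\t100\t300\truby"), bad)
  expect_error(readStateMap(bad, chromSizes = c(`2L` = 1000)),
               "overlap.*line")
  writeLines("2L\t0\t200\tvermilion", bad)
  expect_error(readStateMap(bad, chromSizes = c(`2L` = 1000)),
               "unknown chromatin state")
  writeLines("2L\t300\t200\truby", bad)
  expect_error(readStateMap(bad, chromSizes = c(`2L` = 1000)),
               "malformed")
  writeLines("2L\t0\t300\truby", bad)
  expect_error(readStateMap(bad, chromSizes = c(`2L` = 1000)),
               "200 bp")
})

test_that("gap filling obeys the length boundary and flank-identity rules", {
  rows <- rbind(
    frag("c", 0, 200, "malachite"),    # gap of exactly 400: filled
    frag("c", 200, 600, "gap"),
    frag("c", 600, 800, "malachite"),
    frag("c", 800, 1000, "malachite"), # gap of 600: kept
    frag("c", 1000, 1600, "gap"),
    frag("c", 1600, 1800, "malachite"),
    frag("c", 1800, 2000, "ruby"),     # flanks differ: kept
    frag("c", 2000, 2200, "gap"),
    frag("c", 2200, 2400, "malachite"))
  m <- fillGaps(toyMap(rows, c(c = 2600)))  # trailing gap at chrom end
  st <- as.character(stateFragments(m)$state)
  expect_identical(st[2], "malachite")  # 400 bp boundary value filled
  expect_identical(st[5], "gap")        # 600 bp exceeds the limit
  expect_identical(st[8], "gap")        # ruby|gap|malachite differ
  expect_identical(st[10], "gap")       # chromosome-end gap, one flank

  # 401 bp gap is not filled
  rows2 <- rbind(frag("c", 0, 200, "ruby"),
                 frag("c", 200, 601, "gap"),
                 frag("c", 601, 801, "ruby"))
  m2 <- fillGaps(toyMap(rows2, c(c = 801)))
  expect_identical(as.character(stateFragments(m2)$state)[2], "gap")

  # coordinates never change, only labels; idempotence
  expect_identical(ranges(stateFragments(m)),
                   ranges(stateFragments(toyMap(rows, c(c = 2600)))))
  expect_identical(stateFragments(fillGaps(m)), stateFragments(m))
})

test_that("domain merging creates maximal runs and conserves per-base state", {
  rows <- rbind(tileFrags("c", 0, 3, "ruby"),
                tileFrags("c", 600, 1, "malachite"),
                tileFrags("c", 800, 1, "ruby"),
                frag("c", 1000, 1500, "gap"),
                tileFrags("c", 1500, 2, "ruby"))
  m <- mergeDomains(toyMap(rows, c(c = 1900)))
  dm <- chromatinDomains(m)
  # three abutting ruby fragments -> one domain with nFragments = 3
  expect_equal(start(dm)[1] - 1, 0)
  expect_equal(end(dm)[1], 600)
  expect_equal(dm$nFragments[1], 3L)
  # residual gap breaks the run
  expect_equal(length(dm), 4)
  # alternating states: domain count equals fragment count
  alt <- rbind(tileFrags("c", 0, 1, "ruby"),
               tileFrags("c", 200, 1, "malachite"),
               tileFrags("c", 400, 1, "ruby"),
               tileFrags("c", 600, 1, "malachite"))
  m2 <- mergeDomains(toyMap(alt, c(c = 800)))
  expect_equal(length(chromatinDomains(m2)), 4)
  # conservation: domain bp + residual gap bp = chromosome span
  gapBp <- gapLength(m)
  expect_equal(sum(width(dm)) + gapBp, 1900)
  # per-base state assignment is preserved exactly: for every state the
  # merged domains cover the same bases as the fragments they came from
  fr <- stateFragments(m)
  for (st in chromatinStates()) {
    expect_identical(reduce(granges(dm[dm$state == st])),
                     reduce(granges(fr[fr$state == st])))
  }
})

test_that("clipping restricts domains to regions and keeps parents", {
  dm <- gr0("c", c(100, 2000), c(500, 2400),
            state = factor(c("ruby", "ruby"),
                           levels = chromatinStates()))
  reg <- region0("c", 300, 900)
  seg <- clipToRegions(dm, reg)
  expect_equal(length(seg), 1)
  expect_equal(start(seg) - 1, 300)
  expect_equal(end(seg), 500)
  expect_equal(seg$parentStart, 101)  # whole parent retained
  expect_equal(seg$parentEnd, 500)
  # disjoint domain absent from output
  expect_false(2 %in% seg$parent)
  # region on a missing chromosome errors
  expect_error(clipToRegions(dm, region0("cZ", 0, 100)),
               "absent from the map")
})

test_that("composition is normalized, conserved, and exact on single-state regions", {
  rows <- rbind(tileFrags("c", 0, 5, "ruby"),
                frag("c", 1000, 1600, "gap"),
                tileFrags("c", 1600, 2, "malachite"))
  m <- mergeDomains(toyMap(rows, c(c = 2000)))
  # region fully covered by ruby
  compR <- stateComposition(m, region0("c", 0, 1000))
  expect_equal(compR$fraction[compR$state == "ruby"], 1)
  # with gaps: all five fractions sum to 1 and bp are conserved exactly
  reg <- region0("c", 0, 2000)
  comp <- stateComposition(m, reg, includeGaps = TRUE)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(comp$bp), 2000)
  expect_equal(comp$bp[comp$state == "gap"], 600)
  # empty region set errors
  expect_error(stateComposition(m, GRanges()), "empty region")
})
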