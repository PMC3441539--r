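test_that("fixed-length generator enforces the binding minimum", {
  d <- fixedLengthDistribution(10, 100)
  expect_identical(totalFragments(d), 10L)
  expect_identical(meanLength(d), 100)
  expect_identical(distributionTable(d), data.frame(length = 100L, count = 10L))
  expect_s4_class(fixedLengthDistribution(5, 30), "FragmentDistribution")
  expect_error(fixedLengthDistribution(5, 10), "below Lmin")
  expect_silent(fixedLengthDistribution(5, 10, SimParams(includeIrreparable = TRUE)))
})

test_that("uniform-random generator respects ranges and its seed", {
  d <- uniformRandomDistribution(3, c(20, 200), c(1, 5), seed = 11)
  expect_identical(length(d@lengths), 3L)
  expect_true(all(d@lengths >= 20L & d@lengths <= 200L))
  expect_true(all(d@counts >= 1L & d@counts <= 5L))
  expect_identical(anyDuplicated(d@lengths), 0L)
  d2 <- uniformRandomDistribution(3, c(20, 200), c(1, 5), seed = 11)
  expect_identical(d, d2)
  expect_error(uniformRandomDistribution(10, c(20, 25), c(1, 5)), "distinct lengths")
  # law of large numbers: mean drawn length over many seeds ~ range midpoint
  mids <- vapply(1:300, function(s) {
    mean(uniformRandomDistribution(5, c(20, 200), c(1, 1), seed = s)@lengths)
  }, numeric(1))
  se <- stats::sd(mids) / sqrt(length(mids))
  expect_lt(abs(mean(mids) - 110), 3 * se)
})

test_that("two-class presets apportion short fragments exactly", {
  p <- SimParams()
  fe <- radiationPreset("fe_ion", M0 = 200, seed = 3)
  expect_identical(totalFragments(fe), 200L)
  expect_identical(sum(fe@counts[fe@lengths < criticalLength(p)]), 60L)
  expect_identical(sum(fe@counts[fe@lengths >= criticalLength(p)]), 140L)
  ga <- radiationPreset("gamma", M0 = 200, seed = 3)
  expect_identical(sum(ga@counts[ga@lengths < criticalLength(p)]), 6L)
  expect_identical(sum(ga@counts[ga@lengths >= criticalLength(p)]), 194L)
  # deterministic split regardless of seed; lengths reproducible by seed
  expect_identical(radiationPreset("fe_ion", 200, seed = 3),
    radiationPreset("fe_ion", 200, seed = 3))
  all_long <- twoClassDistribution(50, 0, seed = 1)
  expect_true(all(all_long@lengths >= criticalLength(p)))
  expect_error(twoClassDistribution(50, 0.5, shortRange = c(10, 30)), "shortRange")
  expect_error(twoClassDistribution(50, 0.5, longRange = c(30, 100)), "longRange")
})

test_that("fraction-pair generator splits the three length bands exactly", {
  p <- SimParams()
  half <- as.integer(ceiling(criticalLength(p) / 2))
  d <- fractionPairDistribution(100, 0.2, 0.3, seed = 5)
  lens <- rep(d@lengths, d@counts)
  expect_identical(sum(lens < half), 20L)
  expect_identical(sum(lens >= half & lens < criticalLength(p)), 30L)
  expect_identical(sum(lens >= criticalLength(p)), 50L)
  expect_true(all(lens >= minBindingLength(p)))
  allLong <- fractionPairDistribution(100, 0, 0, seed = 5)
  expect_true(all(allLong@lengths >= criticalLength(p)))
  noLong <- fractionPairDistribution(100, 0.5, 0.5, seed = 5)
  expect_true(all(rep(noLong@lengths, noLong@counts) < criticalLength(p)))
  expect_identical(totalFragments(noLong), 100L)
  expect_error(fractionPairDistribution(100, 0.7, 0.6, seed = 1), "q1")
})

test_that("irreparable fragments are appended to the target fraction", {
  pc <- SimParams(includeIrreparable = TRUE)
  base <- fixedLengthDistribution(70, 100, pc)
  d <- addIrreparable(base, 0.3, seed = 2, params = pc)
  expect_identical(totalFragments(d), 100L)
  expect_identical(countableFragments(d, pc), 70L)
  expect_true(all(d@lengths[d@lengths < minBindingLength(pc)] >= 1L))
  expect_identical(addIrreparable(base, 0, params = pc), base)
  expect_error(addIrreparable(base, 0.3, irrRange = c(10, 25), params = pc), "irrRange")
  expect_error(addIrreparable(base, 0.3, params = SimParams()), "comparison mode")
  expect_error(addIrreparable(base, 1, params = pc), "pIrr")
})

test_that("the TSV distribution format round-trips", {
  d <- FragmentDistribution(c(30, 100, 250), c(2, 5, 1))
  path <- tempfile(fileext = ".tsv")
  writeFragmentDistribution(d, path)
  lines <- readLines(path)
  expect_identical(lines[1], "length\tcount")
  expect_identical(readFragmentDistribution(path), d)
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("size\tcount", "30\t2"), bad)
  expect_error(readFragmentDistribution(bad), "length<TAB>count")
})

test_that("distribution summaries are consistent", {
  d <- FragmentDistribution(c(30, 100), c(2, 2))
  expect_identical(totalFragments(d), 4L)
  expect_identical(totalLength(d), 260)
  expect_identical(meanLength(d), 65)
  expect_identical(shortFraction(d, SimParams()), 0.5)
  expect_identical(countableFragments(d, SimParams()), 4L)
  # duplicated lengths aggregate
  expect_identical(FragmentDistribution(c(30, 30, 100)),
    FragmentDistribution(c(30, 100), c(2, 1)))
})
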