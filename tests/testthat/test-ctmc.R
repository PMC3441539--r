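test_that("state-space enumeration matches hand enumeration", {
  p <- unitParams()
  # two one-site shorts: (F,F) -> (B,F) -> (B,B) -> joined; 4 states
  ss <- enumerateStateSpace(twoShortDist(), p)
  expect_identical(length(ss@keys), 4L)
  expect_identical(sum(ss@absorbing), 1L)
  # two longs: 6 transient {FF,BF,BB} multisets + 3 absorbing end states
  ss2 <- enumerateStateSpace(twoLongDist(), p)
  expect_identical(length(ss2@keys), 9L)
  expect_identical(sum(ss2@absorbing), 3L)
  # single fragment: one absorbing state
  ss1 <- enumerateStateSpace(fixedLengthDistribution(1, 100), p)
  expect_identical(length(ss1@keys), 1L)
  expect_true(all(ss1@absorbing))
  # tractability bound
  expect_error(enumerateStateSpace(fixedLengthDistribution(5, 100), p), "at most 4")
})

test_that("exact mean rejoining times match closed forms", {
  p <- unitParams()
  expect_identical(exactMeanRejoiningTime(fixedLengthDistribution(1, 500), p), 0)
  # two shorts, a = b = 1: 3/(2a) + 1/b = 2.5
  expect_equal(exactMeanRejoiningTime(twoShortDist(), p), 2.5, tolerance = 1e-12)
  # a = 2, b = 1: 1/4 + 1/2 + 1 = 1.75
  p2 <- SimParams(kf = 2)
  expect_equal(exactMeanRejoiningTime(twoShortDist(), p2), 1.75, tolerance = 1e-12)
  expect_equal(closedFormTwoShort(p2), 1.75, tolerance = 1e-12)
  # two longs at unit rates: 35/27 by hand solution of the 6-state chain
  expect_equal(exactMeanRejoiningTime(twoLongDist(), p), 35 / 27, tolerance = 1e-12)
})

test_that("closed form and linear solver agree for random rates", {
  set.seed(301)
  for (r in 1:20) {
    a <- runif(1, 0.05, 5)
    b <- runif(1, 0.05, 5)
    V <- runif(1, 0.2, 4)
    p <- SimParams(kf = a * V, kj = b * V, V = V)  # per-end a, per-pair b
    exact <- exactMeanRejoiningTime(twoShortDist(), p)
    cf <- closedFormTwoShort(a = a, b = b)
    expect_lt(abs(exact - cf) / cf, 1e-10)
  }
  expect_error(closedFormTwoShort(a = -1, b = 1), "positive")
})

test_that("volume rescaling scales the exact mean of bimolecular systems", {
  # all-long systems have no release step; every propensity is ~ 1/V, so the
  # exact mean rejoining time is exactly linear in V
  for (d in list(twoLongDist(), fixedLengthDistribution(3, 100))) {
    t1 <- exactMeanRejoiningTime(d, SimParams(V = 1))
    t2 <- exactMeanRejoiningTime(d, SimParams(V = 2))
    expect_equal(t2, 2 * t1, tolerance = 1e-12)
  }
  # two shorts absorb at the join (no release before absorption), so their
  # mean is also exactly linear in V
  expect_equal(exactMeanRejoiningTime(twoShortDist(), SimParams(V = 2)),
    2 * exactMeanRejoiningTime(twoShortDist(), SimParams(V = 1)),
    tolerance = 1e-12)
  # three shorts must release a residue mid-run; that first-order step does
  # not scale with V, so doubling V less than doubles the mean
  threeShorts <- fixedLengthDistribution(3, 30)
  s1 <- exactMeanRejoiningTime(threeShorts, SimParams(V = 1))
  s2 <- exactMeanRejoiningTime(threeShorts, SimParams(V = 2))
  expect_gt(s2, s1)
  expect_lt(s2, 2 * s1)
})

test_that("transition rates equal channel propensities on decoded states", {
  p <- SimParams(kf = 0.8, kj = 1.7, kr = 0.3)
  ss <- enumerateStateSpace(shortLongDist(), p)
  exit <- tapply(ss@rate, ss@from, sum)
  for (s in as.integer(names(exit))) {
    st <- NHEJsim:::.decodeKey(ss@keys[s], p)
    ch <- NHEJsim:::.enumChannelsIstate(st, p)
    expect_equal(unname(exit[as.character(s)]), sum(ch$propensity))
  }
})
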