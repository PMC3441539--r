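test_that("channel enumeration matches hand counts and propensities", {
  p <- unitParams()
  # two one-site shorts, both FREE: two recruitment channels only
  st <- systemState(twoShortDist(), p)
  ch <- enumerateChannels(st, p)
  expect_identical(ch$kind, c("RECRUIT", "RECRUIT"))
  expect_equal(ch$propensity, rep(recruitRate(p) * proteinCopies(p) / nuclearVolume(p), 2))
  # two longs with (BOUND,BOUND) and (BOUND,FREE): join multiplicity 2*1
  st2 <- systemState(twoLongDist(), p)
  st2 <- applyRecruitment(st2, 1, 1)
  st2 <- applyRecruitment(st2, 1, 2)
  st2 <- applyRecruitment(st2, 2, 1)
  ch2 <- enumerateChannels(st2, p)
  expect_identical(sort(unique(ch2$kind)), c("JOIN", "RECRUIT"))
  expect_identical(sum(ch2$kind == "RECRUIT"), 1L)
  jn <- ch2[ch2$kind == "JOIN", ]
  expect_identical(nrow(jn), 1L)
  expect_equal(jn$propensity, (joinRate(p) / nuclearVolume(p)) * 2 * 1)
  # all fragments below Lmin: nothing can react
  pc <- SimParams(includeIrreparable = TRUE)
  st3 <- systemState(FragmentDistribution(c(10, 15), c(1, 1)), pc)
  expect_identical(nrow(enumerateChannels(st3, pc)), 0L)
  # a residue token contributes one release channel at rate kr
  st4 <- applyJoin(boundPairState(p), 1, 1, 2, 1, p)
  ch4 <- enumerateChannels(st4, p)
  expect_identical(ch4$kind, "RELEASE")
  expect_equal(ch4$propensity, releaseRate(p))
})

test_that("direct-method selection is proportional to propensity", {
  # state with one recruit channel (a = 1) and one release channel (kr = 3)
  p <- SimParams(kr = 3)
  # three shorts; join two of them: leaves one FREE short (recruit channel,
  # propensity 1) and one R-blocked 60-mer (release channel, propensity 3)
  stSel2 <- systemState(fixedLengthDistribution(3, 30), p)
  stSel2 <- applyRecruitment(stSel2, 1, 1)
  stSel2 <- applyRecruitment(stSel2, 2, 1)
  stSel2 <- applyJoin(stSel2, 1, 1, 2, 1, p)   # leaves short 30 FREE + 60 blocked
  ch <- enumerateChannels(stSel2, p)
  expect_identical(ch$kind, c("RECRUIT", "RELEASE"))
  expect_equal(ch$propensity, c(1, 3))
  set.seed(99)
  picks <- vapply(1:2000, function(i) directMethodStep(stSel2, p)$channel$kind, character(1))
  phat <- mean(picks == "RECRUIT")
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(phat - 0.25), 3 * se)
  # waiting time ~ Exponential(a0 = 4)
  set.seed(100)
  taus <- vapply(1:2000, function(i) directMethodStep(stSel2, p)$tau, numeric(1))
  expect_lt(abs(mean(taus) - 1 / 4), 3 * stats::sd(taus) / sqrt(2000))
})

test_that("a state without channels is reported as stalled", {
  pc <- SimParams(includeIrreparable = TRUE)
  st <- systemState(FragmentDistribution(c(10, 12), c(1, 1)), pc)
  step <- directMethodStep(st, pc)
  expect_true(step$stalled)
  tr <- simulateRejoining(FragmentDistribution(c(10, 12), c(1, 1)), pc, seed = 1)
  expect_identical(terminationStatus(tr), "stalled")
})

test_that("the fast selection scan equals the enumerated cumulative scan", {
  p <- SimParams(kf = 0.7, kj = 1.3, kr = 0.4)
  dist <- FragmentDistribution(c(25, 30, 100, 150), c(2, 1, 2, 1))
  st <- NHEJsim:::.istateFromLengths(rep(dist@lengths, dist@counts), p)
  set.seed(7)
  checked <- 0L
  while (NHEJsim:::.istateCountable(st) > 1L) {
    s4 <- NHEJsim:::.istateToS4(st)
    ch <- enumerateChannels(s4, p)
    a0 <- sum(ch$propensity)
    for (u in c(0.037, 0.21, 0.499, 0.83, 0.97)) {
      cs <- cumsum(ch$propensity)
      want <- as.list(ch[which(cs > u * a0)[1L], ])
      got <- NHEJsim:::.fastPick(st, p, u)
      expect_identical(got$kind, want$kind)
      expect_identical(got$i, want$i)
      expect_identical(got$j, want$j)
      expect_identical(got$token, want$token)
      checked <- checked + 1L
    }
    # advance along a random path
    pick <- as.list(ch[sample.int(nrow(ch), 1L), ])
    st <- NHEJsim:::.applyChannelIstate(st, pick, p)
  }
  expect_gt(checked, 50L)
})

test_that("simulation is reproducible and structurally sound", {
  p <- unitParams()
  d <- FragmentDistribution(c(30, 100, 200), c(2, 2, 1))
  t1 <- simulateRejoining(d, p, seed = 42)
  t2 <- simulateRejoining(d, p, seed = 42)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(fragments(finalState(t1)), fragments(finalState(t2)))
  t3 <- simulateRejoining(d, p, seed = 43)
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
  # single fragment: rejoining complete at t = 0 with no events
  tr0 <- simulateRejoining(fixedLengthDistribution(1, 100), p, seed = 1)
  expect_identical(terminationStatus(tr0), "completed")
  expect_identical(length(tr0@times), 0L)
  expect_identical(rejoiningTime(tr0), 0)
  # five longs: always 4 joins, 0 releases
  for (s in 1:10) {
    tr <- simulateRejoining(fixedLengthDistribution(5, 100), p, seed = s)
    ec <- eventCounts(tr)
    expect_identical(ec[["join"]], 4L)
    expect_identical(ec[["release"]], 0L)
  }
  expect_error(simulateRejoining(FragmentDistribution(30, 0)), "positive integers")
})

test_that("the time horizon truncates a run", {
  p <- SimParams(tMax = 1e-4)
  tr <- simulateRejoining(fixedLengthDistribution(10, 100), p, seed = 1)
  expect_identical(terminationStatus(tr), "horizon")
  expect_identical(finalState(tr)@time, 1e-4)
  expect_warning(rejoiningTime(tr), "horizon")
})

test_that("rejoining time is defined by the last join, not trailing releases", {
  # a hand-built log: join at t = 5, release at t = 6
  fs <- systemState(fixedLengthDistribution(1, 100), unitParams())
  tr <- new("Trajectory",
    times = c(5, 6), kinds = c("join", "release"), counts = c(1L, 1L),
    status = "completed", finalState = fs, M0 = 2L, M0countable = 2L,
    seed = 1L, params = unitParams())
  expect_identical(rejoiningTime(tr), 5)
  # consistency with the engine on the two-short system
  sim <- simulateRejoining(twoShortDist(), unitParams(), seed = 5)
  ev <- as.data.frame(sim)
  expect_identical(rejoiningTime(sim), max(ev$time[ev$event == "join"]))
})

test_that("doubling the volume halves every propensity of a bimolecular state", {
  p1 <- SimParams(V = 1)
  p2 <- SimParams(V = 2)
  st <- systemState(fixedLengthDistribution(4, 100), p1)
  st <- applyRecruitment(st, 1, 1)
  st <- applyRecruitment(st, 2, 1)
  ch1 <- enumerateChannels(st, p1)
  ch2 <- enumerateChannels(st, p2)
  expect_equal(ch2$propensity, ch1$propensity / 2)
  expect_equal(sum(ch2$propensity), sum(ch1$propensity) / 2)
})
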