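# Small fixture systems used across the suite. All are built in code; the
# two-short chain has a closed-form mean rejoining time 3/(2a) + 1/b.

unitParams <- function(...) SimParams(...)

twoShortDist <- function() fixedLengthDistribution(2, 30)
shortLongDist <- function() FragmentDistribution(c(30, 100), c(1, 1))
twoLongDist <- function() fixedLengthDistribution(2, 100)
threeMixedDist <- function() FragmentDistribution(c(30, 100, 120), c(1, 1, 1))

# SSA mean rejoining time over n replicates with derived seeds.
ssaTimes <- function(dist, params, n, masterSeed) {
  vapply(seq_len(n), function(i) {
    rejoiningTime(simulateRejoining(dist, params, seed = deriveSeed(masterSeed, i)))
  }, numeric(1))
}

# A two-short state with both ends already bound (join imminent).
boundPairState <- function(params = SimParams()) {
  st <- systemState(twoShortDist(), params)
  st <- applyRecruitment(st, 1, 1)
  applyRecruitment(st, 2, 1)
}

# Difference-of-means z statistic between two ensembles.
zDiff <- function(a, b) {
  se <- sqrt(standardError(a)^2 + standardError(b)^2)
  (meanTime(b) - meanTime(a)) / se
}
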