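test_that("site capacity follows the Ku binding thresholds", {
  p <- unitParams()
  expect_identical(siteCapacity(19, p), 0L)
  expect_identical(siteCapacity(20, p), 1L)
  expect_identical(siteCapacity(41, p), 1L)
  expect_identical(siteCapacity(42, p), 2L)
  expect_identical(siteCapacity(c(10, 30, 1000), p), c(0L, 1L, 2L))
  # thresholds are configurable
  p2 <- SimParams(Lmin = 15L, Lc = 30L)
  expect_identical(siteCapacity(c(14, 15, 29, 30), p2), c(0L, 1L, 1L, 2L))
  expect_error(siteCapacity(0, p), "positive integers")
  expect_error(siteCapacity(10.5, p), "positive integers")
})

test_that("recruitment binds exactly one FREE end and nothing else", {
  p <- unitParams()
  st <- systemState(twoLongDist(), p)
  st2 <- applyRecruitment(st, 1, 1)
  tab <- fragments(st2)
  expect_identical(tab$end1, c("BOUND", "FREE"))
  expect_identical(tab$end2, c("FREE", "FREE"))
  expect_identical(eventCounts(st2)[["recruit"]], 1L)
  # one-site short fragment
  sh <- systemState(fixedLengthDistribution(1, 30), p)
  sh2 <- applyRecruitment(sh, 1, 1)
  expect_identical(fragments(sh2)$end1, "BOUND")
  expect_true(is.na(fragments(sh2)$end2))
  # contract violations
  expect_error(applyRecruitment(st2, 1, 1), "not FREE")
  expect_error(applyRecruitment(sh, 1, 2), "no tracked end")
})

test_that("short+short join leaves a double residue blocking the product", {
  p <- unitParams()
  st <- boundPairState(p)
  st2 <- applyJoin(st, 1, 1, 2, 1, p)
  tab <- fragments(st2)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$length, 60L)
  expect_identical(tab$capacity, 2L)
  expect_identical(tab$end1, "BLOCKED")
  expect_identical(tab$end2, "BLOCKED")
  # one R token blocks both ends
  expect_identical(tab$token1, tab$token2)
  expect_identical(length(residueTokens(st2)), 1L)
  expect_identical(eventCounts(st2)[["join"]], 1L)
})

test_that("short+long join blocks only the short partner's side", {
  p <- unitParams()
  st <- systemState(shortLongDist(), p)
  st <- applyRecruitment(st, 1, 1)  # short's single end
  st <- applyRecruitment(st, 2, 1)  # long's end 1
  st2 <- applyJoin(st, 1, 1, 2, 1, p)
  tab <- fragments(st2)
  expect_identical(tab$length, 130L)
  expect_identical(tab$end1, "BLOCKED")  # short partner's side, r residue
  expect_identical(tab$end2, "FREE")     # inherited from long's non-joining end
  expect_identical(tab$token2, 0L)
  expect_gt(tab$token1, 0L)
})

test_that("long+long join leaves no residue and inherits both ends", {
  p <- unitParams()
  st <- systemState(twoLongDist(), p)
  st <- applyRecruitment(st, 1, 1)
  st <- applyRecruitment(st, 2, 1)
  st <- applyRecruitment(st, 2, 2)
  st2 <- applyJoin(st, 1, 1, 2, 1, p)
  tab <- fragments(st2)
  expect_identical(tab$length, 200L)
  expect_identical(tab$end1, "FREE")   # frag 1's non-joining end
  expect_identical(tab$end2, "BOUND")  # frag 2's non-joining end
  expect_identical(length(residueTokens(st2)), 0L)
})

test_that("join rejects circularization and non-bound ends", {
  p <- unitParams()
  st <- boundPairState(p)
  expect_error(applyJoin(st, 1, 1, 1, 1, p), "itself")
  stFree <- systemState(twoShortDist(), p)
  expect_error(applyJoin(stFree, 1, 1, 2, 1, p), "BOUND")
})

test_that("release frees every end blocked by the token", {
  p <- unitParams()
  st <- applyJoin(boundPairState(p), 1, 1, 2, 1, p)  # fragment(60), R on both ends
  tok <- residueTokens(st)
  st2 <- applyRelease(st, tok, p)
  tab <- fragments(st2)
  expect_identical(tab$end1, "FREE")
  expect_identical(tab$end2, "FREE")
  expect_identical(length(residueTokens(st2)), 0L)
  expect_identical(eventCounts(st2)[["release"]], 1L)
  expect_error(applyRelease(st2, tok, p), "no live residue")
})

test_that("release on a below-critical product leaves one trackable end", {
  p <- unitParams()
  st <- systemState(FragmentDistribution(c(20, 21), c(1, 1)), p)
  st <- applyRecruitment(st, 1, 1)
  st <- applyRecruitment(st, 2, 1)
  st <- applyJoin(st, 1, 1, 2, 1, p)  # 41 bp < Lc = 42: capacity 1
  tab <- fragments(st)
  expect_identical(tab$length, 41L)
  expect_identical(tab$capacity, 1L)
  expect_identical(tab$end1, "BLOCKED")
  expect_true(is.na(tab$end2))
  st2 <- applyRelease(st, residueTokens(st), p)
  tab2 <- fragments(st2)
  expect_identical(tab2$end1, "FREE")
  expect_true(is.na(tab2$end2))
})

test_that("a surviving single residue is inherited through later joins", {
  p <- unitParams()
  # build fragment(130) with r on end1, FREE on end2
  st <- systemState(FragmentDistribution(c(30, 100, 200), c(1, 1, 1)), p)
  st <- applyRecruitment(st, 1, 1)
  st <- applyRecruitment(st, 2, 1)
  st <- applyJoin(st, 1, 1, 2, 1, p)   # fragments now: 200, then 130 (r, FREE)
  tab <- fragments(st)
  expect_identical(tab$length, c(200L, 130L))
  # bind the 130-product's free end and one end of the 200-long, then join
  st <- applyRecruitment(st, 2, 2)
  st <- applyRecruitment(st, 1, 1)
  st2 <- applyJoin(st, 2, 2, 1, 1, p)  # join on the 130's bound end 2
  tab2 <- fragments(st2)
  expect_identical(tab2$length, 330L)
  expect_identical(tab2$end1, "BLOCKED")  # the surviving r residue travelled
  expect_identical(tab2$end2, "FREE")
  expect_identical(length(residueTokens(st2)), 1L)
})

test_that("stochastic trajectories satisfy the structural invariants", {
  p <- unitParams()
  cases <- list(
    FragmentDistribution(c(25, 30, 35), c(2, 1, 2)),
    FragmentDistribution(c(30, 100, 250), c(2, 2, 1)),
    fixedLengthDistribution(6, 100)
  )
  for (ci in seq_along(cases)) {
    dist <- cases[[ci]]
    M0 <- totalFragments(dist)
    bp <- totalLength(dist)
    for (s in 1:5) {
      tr <- simulateRejoining(dist, p, seed = deriveSeed(100 * ci, s))
      expect_identical(terminationStatus(tr), "completed")
      fs <- finalState(tr)
      # total DNA length conserved exactly
      expect_identical(totalLength(fs), bp)
      # exactly M0 - 1 joins from M0 countable fragments to 1
      expect_identical(eventCounts(fs)[["join"]], M0 - 1L)
      # fragment-count log = M0 minus cumulative joins
      ev <- as.data.frame(tr)
      expect_identical(ev$fragments, M0 - cumsum(ev$event == "join"))
      # every BLOCKED end carries a token and vice versa (validity enforces
      # it; run it explicitly on the final state)
      expect_true(validObject(fs))
    }
  }
})

test_that("all-long systems never create residues", {
  p <- unitParams()
  for (s in 1:10) {
    tr <- simulateRejoining(fixedLengthDistribution(5, 100), p, seed = s)
    expect_identical(eventCounts(tr)[["release"]], 0L)
    expect_identical(length(residueTokens(finalState(tr))), 0L)
  }
})

test_that("capacity-0 fragments are inert in comparison mode", {
  p <- SimParams(includeIrreparable = TRUE)
  dist <- FragmentDistribution(c(10, 15, 30, 100), c(1, 1, 2, 2))
  for (s in 1:5) {
    tr <- simulateRejoining(dist, p, seed = s)
    expect_identical(terminationStatus(tr), "completed")
    tab <- fragments(finalState(tr))
    inert <- tab[tab$capacity == 0L, ]
    expect_identical(sort(inert$length), c(10L, 15L))
    expect_true(all(is.na(inert$end1)))
    # countable fragments merged to one; irreparables persist
    expect_identical(countableFragments(finalState(tr)), 1L)
    expect_identical(totalFragments(finalState(tr)), 3L)
  }
  # default mode refuses sub-minimum fragments
  expect_error(systemState(dist, unitParams()), "includeIrreparable")
})
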