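## Reaction-channel enumeration and Gillespie's direct method.
##
## Channel order (fixed, so that a single uniform scanning the cumulative
## propensity is reproducible across platforms):
##   1. RECRUIT channels, by (fragment position, end index);
##   2. JOIN channels, one per unordered fragment pair (i < j, positions
##      lexicographic) with propensity (kj/V) * b_i * b_j, where b is the
##      number of BOUND ends of each partner;
##   3. RELEASE channels, by ascending residue-token id.

.recruitPropensity <- function(params) params@kf * params@nE / params@V

# Bound-end count per fragment.
.boundCounts <- function(st) {
  b1 <- !is.na(st$e1) & st$e1 == .END_BOUND
  b2 <- !is.na(st$e2) & st$e2 == .END_BOUND
  as.integer(b1) + as.integer(b2)
}

# First BOUND end of a fragment (joining-end convention; when both ends are
# bound they are exchangeable in status, so the choice is inconsequential).
.firstBoundEnd <- function(st, i) {
  if (!is.na(st$e1[i]) && st$e1[i] == .END_BOUND) 1L else 2L
}

#' Enumerate the reaction channels of a state
#'
#' One RECRUIT channel per FREE tracked end (propensity `kf*nE/V`), one
#' JOIN channel per unordered pair of distinct fragments with bound ends
#' (propensity `(kj/V) * b_i * b_j`, the number of distinct bound-end
#' pairings), one RELEASE channel per live residue token (propensity `kr`).
#' Capacity-0 (irreparable) fragments contribute no channels. Channels are
#' returned in the fixed documented order used by the direct-method
#' selection scan.
#'
#' @param state a [SystemState-class].
#' @param params a [SimParams-class].
#' @return A `data.frame` with columns `kind`, `i`, `end`, `j`, `endJ`,
#'   `token`, `propensity`; zero rows if no reaction is possible.
#' @examples
#' st <- systemState(fixedLengthDistribution(2, 30), SimParams())
#' enumerateChannels(st, SimParams())
#' @export
enumerateChannels <- function(state, params = SimParams()) {
  stopifnot(is(state, "SystemState"))
  st <- .s4ToIstate(state)
  .enumChannelsIstate(st, params)
}

.enumChannelsIstate <- function(st, params) {
  n <- length(st$len)
  a <- .recruitPropensity(params)
  # RECRUIT: (fragment, end) order.
  f1 <- which(!is.na(st$e1) & st$e1 == .END_FREE)
  f2 <- which(!is.na(st$e2) & st$e2 == .END_FREE)
  fragR <- integer(0); endR <- integer(0)
  if (length(f1) || length(f2)) {
    allf <- sort(unique(c(f1, f2)))
    for (k in allf) {
      if (k %in% f1) { fragR <- c(fragR, k); endR <- c(endR, 1L) }
      if (k %in% f2) { fragR <- c(fragR, k); endR <- c(endR, 2L) }
    }
  }
  # JOIN: pairs i < j with b_i, b_j > 0.
  b <- .boundCounts(st)
  bi <- which(b > 0L)
  ji <- integer(0); jj <- integer(0); jp <- numeric(0)
  if (length(bi) >= 2L) {
    for (x in seq_len(length(bi) - 1L)) {
      for (y in seq.int(x + 1L, length(bi))) {
        ji <- c(ji, bi[x]); jj <- c(jj, bi[y])
        jp <- c(jp, (params@kj / params@V) * b[bi[x]] * b[bi[y]])
      }
    }
  }
  toks <- .liveTokens(st)
  kind <- c(
    rep("RECRUIT", length(fragR)),
    rep("JOIN", length(ji)),
    rep("RELEASE", length(toks))
  )
  out <- data.frame(
    kind = kind,
    i = c(fragR, ji, rep(NA_integer_, length(toks))),
    end = c(endR, vapply(ji, function(k) .firstBoundEnd(st, k), integer(1)),
      rep(NA_integer_, length(toks))),
    j = c(rep(NA_integer_, length(fragR)), jj, rep(NA_integer_, length(toks))),
    endJ = c(rep(NA_integer_, length(fragR)),
      vapply(jj, function(k) .firstBoundEnd(st, k), integer(1)),
      rep(NA_integer_, length(toks))),
    token = c(rep(NA_integer_, length(fragR) + length(ji)), toks),
    propensity = c(rep(a, length(fragR)), jp, rep(params@kr, length(toks))),
    stringsAsFactors = FALSE
  )
  out[out$propensity > 0, , drop = FALSE]
}

# Aggregate propensities, O(n): recruit total, join total, release total.
.propensityTotals <- function(st, params) {
  a <- .recruitPropensity(params)
  nFree <- sum(st$e1 == .END_FREE, na.rm = TRUE) + sum(st$e2 == .END_FREE, na.rm = TRUE)
  b <- .boundCounts(st)
  B <- sum(b)
  joinTot <- (params@kj / params@V) * (B * B - sum(b * b)) / 2
  toks <- .liveTokens(st)
  list(
    recruitTot = a * nFree, joinTot = joinTot,
    releaseTot = params@kr * length(toks),
    a0 = a * nFree + joinTot + params@kr * length(toks),
    b = b, toks = toks, nFree = nFree
  )
}

# Single-uniform channel selection scanning the cumulative propensity in
# the documented order, implemented blockwise in O(n). Mathematically
# identical to scanning the rows of .enumChannelsIstate().
.fastPick <- function(st, params, u, tot = .propensityTotals(st, params)) {
  x <- u * tot$a0
  a <- .recruitPropensity(params)
  if (tot$recruitTot > 0 && x < tot$recruitTot) {
    k <- min(tot$nFree, floor(x / a) + 1)
    # k-th FREE end in (fragment, end) order
    free1 <- !is.na(st$e1) & st$e1 == .END_FREE
    free2 <- !is.na(st$e2) & st$e2 == .END_FREE
    n <- length(st$len)
    fragSeq <- rep(seq_len(n), each = 2L)
    endSeq <- rep(c(1L, 2L), n)
    freeSeq <- c(rbind(free1, free2))
    hit <- which(freeSeq)[k]
    return(list(kind = "RECRUIT",
      i = fragSeq[hit], end = endSeq[hit], j = NA_integer_,
      endJ = NA_integer_, token = NA_integer_))
  }
  x <- x - tot$recruitTot
  if (tot$joinTot > 0 && x < tot$joinTot) {
    kjV <- params@kj / params@V
    b <- tot$b
    # block weight of pair-block i: b_i * (sum of b_j for j > i)
    suffix <- rev(cumsum(rev(b))) - b
    w <- kjV * b * suffix
    cs <- cumsum(w)
    i <- which(cs > x)[1L]
    if (is.na(i)) i <- max(which(w > 0))  # float guard at the upper edge
    rem <- x - if (i > 1L) cs[i - 1L] else 0
    cand <- which(b > 0L)
    cand <- cand[cand > i]
    csj <- cumsum(kjV * b[i] * b[cand])
    jdx <- which(csj > rem)[1L]
    if (is.na(jdx)) jdx <- length(cand)
    j <- cand[jdx]
    return(list(kind = "JOIN", i = i, end = .firstBoundEnd(st, i),
      j = j, endJ = .firstBoundEnd(st, j), token = NA_integer_))
  }
  x <- x - tot$joinTot
  k <- min(length(tot$toks), floor(x / params@kr) + 1)
  list(kind = "RELEASE", i = NA_integer_, end = NA_integer_,
    j = NA_integer_, endJ = NA_integer_, token = tot$toks[k])
}

.applyChannelIstate <- function(st, ch, params) {
  switch(ch$kind,
    RECRUIT = .istateRecruit(st, ch$i, ch$end),
    JOIN = .istateJoin(st, ch$i, ch$end, ch$j, ch$endJ, params),
    RELEASE = .istateRelease(st, ch$token),
    stop("unknown channel kind: ", ch$kind)
  )
}

#' Execute one channel on a state
#'
#' @param state a [SystemState-class].
#' @param channel a one-row channel (a row of [enumerateChannels()] or the
#'   channel returned by [directMethodStep()]).
#' @param params a [SimParams-class].
#' @return The updated [SystemState-class].
#' @export
applyChannel <- function(state, channel, params = SimParams()) {
  stopifnot(is(state, "SystemState"))
  ch <- as.list(channel)
  .istateToS4(.applyChannelIstate(.s4ToIstate(state), ch, params))
}

#' One step of Gillespie's direct method
#'
#' Draws the exponential waiting time (total propensity `a0`) and selects a
#' channel with probability proportional to its propensity, by a single
#' uniform draw scanning the cumulative propensity in the documented
#' channel order. Uses and advances R's global RNG stream: one `rexp` draw
#' for the time, then one `runif` draw for the selection.
#'
#' @param state a [SystemState-class].
#' @param params a [SimParams-class].
#' @return A list with `tau` (waiting time), `channel` (a one-row channel
#'   `data.frame`) and `stalled`. If no channel has positive propensity,
#'   `stalled = TRUE` and `tau`/`channel` are `NA`/`NULL`.
#' @export
directMethodStep <- function(state, params = SimParams()) {
  stopifnot(is(state, "SystemState"))
  channels <- enumerateChannels(state, params)
  a0 <- sum(channels$propensity)
  if (a0 <= 0) {
    return(list(tau = NA_real_, channel = NULL, stalled = TRUE))
  }
  tau <- rexp(1L, a0)
  u <- runif(1L)
  cs <- cumsum(channels$propensity)
  pick <- which(cs > u * a0)[1L]
  if (is.na(pick)) pick <- nrow(channels)
  list(tau = tau, channel = channels[pick, , drop = FALSE], stalled = FALSE)
}

#' Simulate the rejoining of a fragment distribution
#'
#' Runs Gillespie's direct method from the initial distribution until the
#' countable fragments have merged into a single fragment ("completed"),
#' the time horizon is reached ("horizon"), or no reaction channel remains
#' while more than one countable fragment persists ("stalled"; only
#' possible in comparison mode). Reproducible: the same
#' (distribution, params, seed) triple yields a bit-identical trajectory.
#'
#' @param dist a [FragmentDistribution-class].
#' @param params a [SimParams-class].
#' @param seed RNG seed (`NULL` = current stream, not reproducible).
#' @param tMax time horizon; defaults to `timeHorizon(params)`.
#' @return A [Trajectory-class].
#' @examples
#' tr <- simulateRejoining(fixedLengthDistribution(5, 100), SimParams(), seed = 1)
#' rejoiningTime(tr)
#' eventCounts(finalState(tr))
#' @export
simulateRejoining <- function(dist, params = SimParams(), seed = NULL,
                              tMax = timeHorizon(params)) {
  stopifnot(is(dist, "FragmentDistribution"))
  st <- .istateFromLengths(rep(dist@lengths, dist@counts), params)
  M0 <- length(st$len)
  .withSeed(seed, {
    cap <- 6L * M0 + 16L
    evTime <- numeric(cap); evKind <- integer(cap); evCount <- integer(cap)
    nev <- 0L
    status <- NULL
    repeat {
      if (.istateCountable(st) == 1L) { status <- "completed"; break }
      tot <- .propensityTotals(st, params)
      if (tot$a0 <= 0) { status <- "stalled"; break }
      tau <- rexp(1L, tot$a0)
      if (st$time + tau > tMax) { st$time <- tMax; status <- "horizon"; break }
      u <- runif(1L)
      ch <- .fastPick(st, params, u, tot)
      st <- .applyChannelIstate(st, ch, params)
      st$time <- st$time + tau
      nev <- nev + 1L
      if (nev > cap) {
        cap <- cap * 2L
        length(evTime) <- cap; length(evKind) <- cap; length(evCount) <- cap
      }
      evTime[nev] <- st$time
      evKind[nev] <- switch(ch$kind, RECRUIT = 1L, JOIN = 2L, RELEASE = 3L)
      evCount[nev] <- length(st$len)
    }
    new("Trajectory",
      times = evTime[seq_len(nev)],
      kinds = c("recruit", "join", "release")[evKind[seq_len(nev)]],
      counts = evCount[seq_len(nev)],
      status = status, finalState = .istateToS4(st),
      M0 = M0, M0countable = st$countable0,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      params = params
    )
  })
}

#' @describeIn rejoiningTime time of the last join event of a completed
#'   trajectory.
#' @export
setMethod("rejoiningTime", "Trajectory", function(x) {
  if (x@status != "completed") {
    warning("rejoining time is undefined for a '", x@status, "' trajectory")
    return(NA_real_)
  }
  if (x@M0countable <= 1L) return(0)
  max(x@times[x@kinds == "join"])
})

#' Trajectory utilities
#'
#' `terminationStatus` reports how the run ended; `finalState` returns the
#' terminal [SystemState-class]; `eventCounts` the per-class event tallies.
#'
#' @param x a [Trajectory-class].
#' @name Trajectory-utils
NULL

#' @rdname Trajectory-utils
#' @export
setMethod("terminationStatus", "Trajectory", function(x) x@status)
#' @rdname Trajectory-utils
#' @export
setMethod("finalState", "Trajectory", function(x) x@finalState)
#' @rdname Trajectory-utils
#' @export
setMethod("eventCounts", "Trajectory", function(x) eventCounts(x@finalState))

#' @describeIn Trajectory-utils event log as a `data.frame`
#'   (`time`, `event`, `fragments`).
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.Trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time = x@times, event = x@kinds, fragments = x@counts)
}

setMethod("show", "Trajectory", function(object) {
  cat(sprintf(
    "Trajectory: %d events, status '%s'; M0 = %d (%d countable)\n",
    length(object@times), object@status, object@M0, object@M0countable
  ))
  ec <- eventCounts(object@finalState)
  cat(sprintf("  events: %d recruit, %d join, %d release; final t = %g\n",
    ec[["recruit"]], ec[["join"]], ec[["release"]], object@finalState@time))
  if (object@status == "completed") {
    cat(sprintf("  rejoining time: %g\n", rejoiningTime(object)))
  }
  invisible(NULL)
})
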