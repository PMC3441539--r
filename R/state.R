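#' Binding-site capacity of a fragment
#'
#' Number of repair-protein (Ku) binding ends a fragment of a given length
#' can hold simultaneously: 0 below the minimum binding length `Lmin`
#' (irreparable), 1 between `Lmin` and the critical length `Lc` (one end at
#' a time), 2 at `Lc` and above (both ends).
#'
#' @param length fragment length(s) in bp (positive integers).
#' @param params a [SimParams-class].
#' @return Integer vector of capacities in `{0, 1, 2}`.
#' @examples
#' siteCapacity(c(19, 20, 41, 42), SimParams())
#' @export
siteCapacity <- function(length, params = SimParams()) {
  length <- .assertWholeLengths(length)
  .capOf(length, params@Lmin, params@Lc)
}

.capOf <- function(len, Lmin, Lc) {
  out <- integer(length(len))
  out[len >= Lmin] <- 1L
  out[len >= Lc] <- 2L
  out
}

## ---- internal list-state -------------------------------------------------
## Mirrors the SystemState slots; the SSA loop mutates this directly.

.istateFromLengths <- function(lengths, params, check = TRUE) {
  lengths <- .assertWholeLengths(lengths)
  cap <- .capOf(lengths, params@Lmin, params@Lc)
  if (check && !params@includeIrreparable && any(cap == 0L)) {
    stop(sprintf(
      "fragments shorter than Lmin = %d bp cannot bind Ku; enable 'includeIrreparable' to keep them",
      params@Lmin
    ), call. = FALSE)
  }
  n <- length(lengths)
  e1 <- rep(NA_integer_, n); e1[cap >= 1L] <- .END_FREE
  e2 <- rep(NA_integer_, n); e2[cap >= 2L] <- .END_FREE
  list(
    len = lengths, cap = cap, e1 = e1, e2 = e2,
    t1 = integer(n), t2 = integer(n),
    nextToken = 1L, time = 0,
    nRecruit = 0L, nJoin = 0L, nRelease = 0L,
    countable0 = sum(cap >= 1L)
  )
}

.getEnd <- function(st, i, end) if (end == 1L) st$e1[i] else st$e2[i]
.getTok <- function(st, i, end) if (end == 1L) st$t1[i] else st$t2[i]

.checkFragIndex <- function(st, i) {
  if (!.isCount(i) || i > length(st$len)) {
    stop("fragment index out of range", call. = FALSE)
  }
}

.checkEndIndex <- function(st, i, end) {
  if (!.isCount(end) || end > 2L) stop("end index must be 1 or 2", call. = FALSE)
  if (end > st$cap[i]) {
    stop(sprintf("fragment %d (capacity %d) has no tracked end %d", i, st$cap[i], end),
      call. = FALSE)
  }
}

.istateRecruit <- function(st, i, end) {
  .checkFragIndex(st, i)
  .checkEndIndex(st, i, end)
  if (.getEnd(st, i, end) != .END_FREE) {
    stop(sprintf("recruitment contract violation: end %d of fragment %d is not FREE", end, i),
      call. = FALSE)
  }
  if (end == 1L) st$e1[i] <- .END_BOUND else st$e2[i] <- .END_BOUND
  st$nRecruit <- st$nRecruit + 1L
  st
}

.istateJoin <- function(st, i, ei, j, ej, params) {
  .checkFragIndex(st, i); .checkFragIndex(st, j)
  if (i == j) stop("cannot join a fragment to itself (circularization is disallowed)", call. = FALSE)
  .checkEndIndex(st, i, ei); .checkEndIndex(st, j, ej)
  if (.getEnd(st, i, ei) != .END_BOUND || .getEnd(st, j, ej) != .END_BOUND) {
    stop("join contract violation: both addressed ends must be BOUND", call. = FALSE)
  }
  newlen <- st$len[i] + st$len[j]
  newcap <- .capOf(newlen, params@Lmin, params@Lc)
  capi <- st$cap[i]; capj <- st$cap[j]
  tok <- st$nextToken
  if (capi == 1L && capj == 1L) {
    # short + short: a double residue (R) blocks every tracked end of the
    # product; released by one event.
    if (newcap == 1L) {
      ne1 <- .END_BLOCKED; nt1 <- tok; ne2 <- NA_integer_; nt2 <- 0L
    } else {
      ne1 <- .END_BLOCKED; nt1 <- tok; ne2 <- .END_BLOCKED; nt2 <- tok
    }
    st$nextToken <- tok + 1L
  } else if (capi == 1L || capj == 1L) {
    # short + long: product is always long (>= Lc); a single residue (r)
    # blocks the product end on the short partner's side, the long side
    # inherits the long partner's non-joining end (with any surviving
    # single residue).
    if (capi == 1L) {
      lj <- j; le <- 3L - ej
    } else {
      lj <- i; le <- 3L - ei
    }
    inhE <- .getEnd(st, lj, le)
    inhT <- .getTok(st, lj, le)
    if (capi == 1L) {
      ne1 <- .END_BLOCKED; nt1 <- tok; ne2 <- inhE; nt2 <- inhT
    } else {
      ne1 <- inhE; nt1 <- inhT; ne2 <- .END_BLOCKED; nt2 <- tok
    }
    st$nextToken <- tok + 1L
  } else {
    # long + long: the junction residue never obstructs an end; the two
    # product ends inherit the two non-joining ends unchanged.
    oi <- 3L - ei; oj <- 3L - ej
    ne1 <- .getEnd(st, i, oi); nt1 <- .getTok(st, i, oi)
    ne2 <- .getEnd(st, j, oj); nt2 <- .getTok(st, j, oj)
  }
  keep <- setdiff(seq_along(st$len), c(i, j))
  st$len <- c(st$len[keep], newlen)
  st$cap <- c(st$cap[keep], newcap)
  st$e1 <- c(st$e1[keep], ne1)
  st$e2 <- c(st$e2[keep], ne2)
  st$t1 <- c(st$t1[keep], nt1)
  st$t2 <- c(st$t2[keep], nt2)
  st$nJoin <- st$nJoin + 1L
  st
}

.liveTokens <- function(st) {
  sort(unique(c(st$t1[st$t1 > 0L], st$t2[st$t2 > 0L])))
}

.istateRelease <- function(st, token) {
  if (!.isCount(token)) stop("residue token id must be a positive integer", call. = FALSE)
  hit1 <- which(st$t1 == token)
  hit2 <- which(st$t2 == token)
  if (!length(hit1) && !length(hit2)) {
    stop(sprintf("release contract violation: no live residue token %d", token), call. = FALSE)
  }
  st$e1[hit1] <- .END_FREE; st$t1[hit1] <- 0L
  st$e2[hit2] <- .END_FREE; st$t2[hit2] <- 0L
  st$nRelease <- st$nRelease + 1L
  st
}

.istateCountable <- function(st) sum(st$cap >= 1L)

## ---- S4 surface ----------------------------------------------------------

.istateToS4 <- function(st) {
  new("SystemState",
    len = st$len, cap = st$cap, e1 = st$e1, e2 = st$e2,
    t1 = st$t1, t2 = st$t2, nextToken = st$nextToken, time = st$time,
    nRecruit = st$nRecruit, nJoin = st$nJoin, nRelease = st$nRelease,
    countable0 = st$countable0
  )
}

.s4ToIstate <- function(state) {
  list(
    len = state@len, cap = state@cap, e1 = state@e1, e2 = state@e2,
    t1 = state@t1, t2 = state@t2, nextToken = state@nextToken,
    time = state@time, nRecruit = state@nRecruit, nJoin = state@nJoin,
    nRelease = state@nRelease, countable0 = state@countable0
  )
}

#' Build the initial system state of a fragment distribution
#'
#' Expands a [FragmentDistribution-class] into one fragment per copy, all
#' tracked ends FREE, no residues, time zero. Fragments below `Lmin` are
#' rejected unless the parameter set enables comparison mode, in which case
#' they are kept as inert capacity-0 species.
#'
#' @param dist a [FragmentDistribution-class].
#' @param params a [SimParams-class].
#' @return A [SystemState-class].
#' @examples
#' st <- systemState(fixedLengthDistribution(2, 30), SimParams())
#' fragments(st)
#' @export
systemState <- function(dist, params = SimParams()) {
  stopifnot(is(dist, "FragmentDistribution"))
  .istateToS4(.istateFromLengths(rep(dist@lengths, dist@counts), params))
}

#' Apply one recruitment event
#'
#' Binds one repair protein to a FREE tracked end, making it BOUND.
#' Recruitment is irreversible and does not deplete the protein pool.
#'
#' @param state a [SystemState-class].
#' @param fragment fragment index (row in `fragments(state)`).
#' @param end tracked end index (1 or 2).
#' @return The updated [SystemState-class].
#' @export
applyRecruitment <- function(state, fragment, end = 1L) {
  stopifnot(is(state, "SystemState"))
  .istateToS4(.istateRecruit(.s4ToIstate(state), as.integer(fragment), as.integer(end)))
}

#' Apply one joining event
#'
#' Joins two distinct fragments at two BOUND ends into a single fragment of
#' summed length. The residue rule depends on the partners' capacities
#' before the join: two one-site (short) partners leave a double residue R
#' blocking every tracked end of the product; a short and a two-site (long)
#' partner leave a single residue r blocking the product end on the short
#' partner's side while the long side inherits the long partner's
#' non-joining end; two long partners leave no obstructing residue and both
#' product ends inherit the non-joining ends. Self-joining (circularization)
#' is disallowed.
#'
#' @param state a [SystemState-class].
#' @param fragmentA,fragmentB indices of the two fragments.
#' @param endA,endB the joining (BOUND) end of each.
#' @param params a [SimParams-class].
#' @return The updated [SystemState-class]; the product fragment is the last
#'   row, with end 1 on `fragmentA`'s side and end 2 on `fragmentB`'s side.
#' @export
applyJoin <- function(state, fragmentA, endA, fragmentB, endB, params = SimParams()) {
  stopifnot(is(state, "SystemState"))
  .istateToS4(.istateJoin(
    .s4ToIstate(state),
    as.integer(fragmentA), as.integer(endA),
    as.integer(fragmentB), as.integer(endB), params
  ))
}

#' Apply one residue release event
#'
#' Removes a residue token; every end it blocked becomes FREE. A double
#' residue (R, blocking both ends of a short+short product) is cleared by
#' this single event.
#'
#' @param state a [SystemState-class].
#' @param token residue token id (see `fragments(state)`).
#' @param params unused; kept for interface symmetry.
#' @return The updated [SystemState-class].
#' @export
applyRelease <- function(state, token, params = SimParams()) {
  stopifnot(is(state, "SystemState"))
  .istateToS4(.istateRelease(.s4ToIstate(state), as.integer(token)))
}

#' @describeIn fragments fragment table of a [SystemState-class].
#' @export
setMethod("fragments", "SystemState", function(x) {
  data.frame(
    length = x@len, capacity = x@cap,
    end1 = .endLabel(x@e1), end2 = .endLabel(x@e2),
    token1 = x@t1, token2 = x@t2
  )
})

#' @describeIn totalFragments number of fragments in a state.
#' @export
setMethod("totalFragments", "SystemState", function(x, ...) length(x@len))
#' @describeIn totalFragments number of countable (capacity >= 1) fragments.
#' @export
setMethod("countableFragments", "SystemState", function(x, ...) sum(x@cap >= 1L))
#' @describeIn totalFragments total DNA length (bp) in a state; conserved by
#'   every reaction.
#' @export
setMethod("totalLength", "SystemState", function(x, ...) sum(as.numeric(x@len)))

#' Residue tokens alive in a state
#'
#' @param state a [SystemState-class].
#' @return Integer vector of live residue-token ids (sorted).
#' @export
residueTokens <- function(state) {
  stopifnot(is(state, "SystemState"))
  .liveTokens(.s4ToIstate(state))
}

#' @describeIn eventCounts event tallies of a state.
#' @export
setMethod("eventCounts", "SystemState", function(x) {
  c(recruit = x@nRecruit, join = x@nJoin, release = x@nRelease)
})

setMethod("show", "SystemState", function(object) {
  cat(sprintf(
    "SystemState: %d fragment(s) (%d countable), %d residue token(s), t = %g\n",
    length(object@len), sum(object@cap >= 1L),
    length(.liveTokens(.s4ToIstate(object))), object@time
  ))
  cat(sprintf("  events: %d recruit, %d join, %d release\n",
    object@nRecruit, object@nJoin, object@nRelease))
  tab <- fragments(object)
  if (nrow(tab) <= 10L) {
    print(tab)
  } else {
    print(utils::head(tab, 10L))
    cat(sprintf("  ... %d more fragments\n", nrow(tab) - 10L))
  }
  invisible(NULL)
})
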