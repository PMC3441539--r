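## Exact continuous-time Markov chain of a small rejoining system.
##
## Canonicalization: fragment identity and end labelling are quotiented
## out. Each fragment is encoded as "<length>/<end code>", where the end
## code has one character per tracked end, sorted within the fragment:
##   F free, B bound, r blocked by a single residue (its own token),
##   and "RR" for a double residue (one token blocking both ends).
## Capacity-0 fragments encode as "<length>/-". A state key is the
## comma-joined sorted multiset of fragment encodings. The channel
## propensities depend only on status counts, so this lumping is strongly
## lumpable and preserves first-passage times.

.MAX_ORACLE_FRAGMENTS <- 4L
.MAX_ORACLE_STATES <- 50000L

.encodeIstate <- function(st) {
  n <- length(st$len)
  enc <- character(n)
  for (i in seq_len(n)) {
    if (st$cap[i] == 0L) {
      enc[i] <- paste0(st$len[i], "/-")
    } else {
      chars <- character(0)
      shared <- st$cap[i] == 2L && st$t1[i] > 0L && st$t1[i] == st$t2[i]
      for (end in seq_len(st$cap[i])) {
        e <- .getEnd(st, i, end)
        chars <- c(chars, if (e == .END_FREE) "F" else if (e == .END_BOUND) "B"
        else if (shared) "R" else "r")
      }
      enc[i] <- paste0(st$len[i], "/", paste(sort(chars, method = "radix"), collapse = ""))
    }
  }
  paste(sort(enc, method = "radix"), collapse = ",")
}

.decodeKey <- function(key, params) {
  parts <- strsplit(key, ",", fixed = TRUE)[[1L]]
  n <- length(parts)
  len <- integer(n); e1 <- rep(NA_integer_, n); e2 <- rep(NA_integer_, n)
  t1 <- integer(n); t2 <- integer(n)
  tok <- 1L
  for (i in seq_len(n)) {
    bits <- strsplit(parts[i], "/", fixed = TRUE)[[1L]]
    len[i] <- as.integer(bits[1L])
    code <- bits[2L]
    if (code != "-") {
      chars <- strsplit(code, "", fixed = TRUE)[[1L]]
      if (identical(chars, c("R", "R"))) {
        e1[i] <- .END_BLOCKED; e2[i] <- .END_BLOCKED
        t1[i] <- tok; t2[i] <- tok; tok <- tok + 1L
      } else {
        for (end in seq_along(chars)) {
          code1 <- chars[end]
          e <- if (code1 == "F") .END_FREE else if (code1 == "B") .END_BOUND else .END_BLOCKED
          t <- 0L
          if (code1 %in% c("r", "R")) { t <- tok; tok <- tok + 1L }
          if (end == 1L) { e1[i] <- e; t1[i] <- t } else { e2[i] <- e; t2[i] <- t }
        }
      }
    }
  }
  cap <- .capOf(len, params@Lmin, params@Lc)
  list(
    len = len, cap = cap, e1 = e1, e2 = e2, t1 = t1, t2 = t2,
    nextToken = tok, time = 0,
    nRecruit = 0L, nJoin = 0L, nRelease = 0L,
    countable0 = sum(cap >= 1L)
  )
}

#' Enumerate the exact state space of a small rejoining system
#'
#' Breadth-first expansion of every reachable state of the reaction
#' network, using the same state-update rules as the stochastic engine, so
#' that transition rates equal the channel propensities exactly. States are
#' canonicalized (fragments unordered, end labelling symmetrized), which
#' preserves the mean first-passage time. States with a single countable
#' fragment are absorbing and are not expanded further.
#'
#' Only small systems are tractable: at most 4 initial countable fragments.
#'
#' @param dist a [FragmentDistribution-class].
#' @param params a [SimParams-class].
#' @return A [StateSpace-class].
#' @examples
#' ss <- enumerateStateSpace(fixedLengthDistribution(2, 30), SimParams())
#' length(ss@keys)
#' @export
enumerateStateSpace <- function(dist, params = SimParams()) {
  stopifnot(is(dist, "FragmentDistribution"))
  st0 <- .istateFromLengths(rep(dist@lengths, dist@counts), params)
  if (st0$countable0 > .MAX_ORACLE_FRAGMENTS) {
    stop(sprintf("exact enumeration supports at most %d countable fragments (got %d)",
      .MAX_ORACLE_FRAGMENTS, st0$countable0), call. = FALSE)
  }
  key0 <- .encodeIstate(st0)
  index <- new.env(parent = emptyenv())
  assign(key0, 1L, envir = index)
  keys <- key0
  absorbing <- .istateCountable(st0) <= 1L
  frontier <- if (absorbing) integer(0) else 1L
  from <- integer(0); to <- integer(0); rate <- numeric(0)
  while (length(frontier)) {
    nxt <- integer(0)
    for (s in frontier) {
      st <- .decodeKey(keys[s], params)
      channels <- .enumChannelsIstate(st, params)
      if (!nrow(channels)) next
      # aggregate rates into canonical targets
      agg <- new.env(parent = emptyenv())
      for (r in seq_len(nrow(channels))) {
        ch <- as.list(channels[r, ])
        st2 <- .applyChannelIstate(st, ch, params)
        k2 <- .encodeIstate(st2)
        assign(k2, (if (exists(k2, envir = agg, inherits = FALSE))
          get(k2, envir = agg) else 0) + ch$propensity, envir = agg)
      }
      for (k2 in sort(ls(agg), method = "radix")) {
        if (!exists(k2, envir = index, inherits = FALSE)) {
          keys <- c(keys, k2)
          idx2 <- length(keys)
          assign(k2, idx2, envir = index)
          st2 <- .decodeKey(k2, params)
          abs2 <- .istateCountable(st2) <= 1L
          absorbing <- c(absorbing, abs2)
          if (!abs2) nxt <- c(nxt, idx2)
          if (length(keys) > .MAX_ORACLE_STATES) {
            stop("state space exceeds the tractable bound", call. = FALSE)
          }
        }
        idx2 <- get(k2, envir = index)
        from <- c(from, s); to <- c(to, idx2)
        rate <- c(rate, get(k2, envir = agg))
      }
    }
    frontier <- nxt
  }
  new("StateSpace",
    keys = keys, from = from, to = to, rate = rate,
    absorbing = absorbing, initial = 1L
  )
}

#' Exact mean rejoining time of a small system
#'
#' Solves the first-passage linear system of the exact Markov chain: for
#' every transient (non-absorbing) state `s` with exit rate `q_s`,
#' `h_s = 1/q_s + sum_t (q_st / q_s) h_t`, absorbing states having
#' `h = 0`. The returned value is `h` at the initial state — the exact
#' expected time from the initial countable fragments down to one.
#' Absorption is defined on countable-fragment count alone, so release
#' events after the final join do not contribute (matching the
#' rejoining-time definition of the stochastic engine). Dense LU solve;
#' accurate to solver tolerance (<= 1e-10 relative on these small systems).
#'
#' @param dist a [FragmentDistribution-class] (at most 4 countable
#'   fragments).
#' @param params a [SimParams-class].
#' @return The exact mean rejoining time (single number).
#' @examples
#' exactMeanRejoiningTime(fixedLengthDistribution(2, 30), SimParams())
#' @export
exactMeanRejoiningTime <- function(dist, params = SimParams()) {
  ss <- enumerateStateSpace(dist, params)
  if (ss@absorbing[ss@initial]) return(0)
  transient <- which(!ss@absorbing)
  nt <- length(transient)
  pos <- integer(length(ss@keys))
  pos[transient] <- seq_len(nt)
  A <- diag(nt)
  rhs <- numeric(nt)
  exit <- numeric(length(ss@keys))
  for (e in seq_along(ss@from)) exit[ss@from[e]] <- exit[ss@from[e]] + ss@rate[e]
  if (any(exit[transient] <= 0)) {
    stop("singular first-passage system: a transient state has no exit rate",
      call. = FALSE)
  }
  rhs <- 1 / exit[transient]
  for (e in seq_along(ss@from)) {
    s <- ss@from[e]; t <- ss@to[e]
    if (!ss@absorbing[t]) {
      A[pos[s], pos[t]] <- A[pos[s], pos[t]] - ss@rate[e] / exit[s]
    }
  }
  h <- solve(A, rhs)
  h[pos[ss@initial]]
}

#' Closed-form mean rejoining time of two one-site fragments
#'
#' For two short (capacity-1) fragments the chain is a three-step path:
#' first recruitment at rate `2a`, second at rate `a`, join at rate `b`,
#' with `a = kf*nE/V` per free end and `b = kj/V`. The mean first-passage
#' time is `1/(2a) + 1/a + 1/b = 3/(2a) + 1/b`. Used as an analytic anchor
#' for the exact solver and the stochastic engine.
#'
#' @param params a [SimParams-class]; alternatively supply `a` and `b`
#'   directly.
#' @param a recruitment propensity per free end.
#' @param b joining propensity of the bound pair.
#' @return The exact mean rejoining time.
#' @examples
#' closedFormTwoShort(a = 1, b = 1)  # 2.5
#' @export
closedFormTwoShort <- function(params = SimParams(), a = NULL, b = NULL) {
  if (is.null(a)) a <- .recruitPropensity(params)
  if (is.null(b)) b <- params@kj / params@V
  if (!.isNumber(a) || !.isNumber(b) || a <= 0 || b <= 0) {
    stop("'a' and 'b' must be positive", call. = FALSE)
  }
  3 / (2 * a) + 1 / b
}

setMethod("show", "StateSpace", function(object) {
  cat(sprintf(
    "StateSpace: %d states (%d absorbing), %d transitions\n",
    length(object@keys), sum(object@absorbing), length(object@from)
  ))
  cat("  initial: ", object@keys[object@initial], "\n")
  invisible(NULL)
})
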