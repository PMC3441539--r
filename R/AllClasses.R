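#' SimParams: kinetic parameters of the rejoining model
#'
#' Container for every rate constant and threshold of the fragment-rejoining
#' reaction network. All units are arbitrary but must be mutually consistent:
#' time and volume enter only through the pseudo-first-order combinations
#' `kf * nE / V` (recruitment per free end), `kj / V` (joining per bound-end
#' pair) and `kr` (release per residue), so results are covariant under a
#' common rescaling of time and volume units.
#'
#' @slot kf bimolecular recruitment rate constant of the repair protein
#'   (volume / time, per free end and protein copy).
#' @slot nE constant copy number of the repair protein (Ku); the protein is
#'   assumed abundant, so recruitment never depletes it.
#' @slot kj bimolecular joining rate constant (volume / time, per pair of
#'   protein-bound ends on distinct fragments).
#' @slot kr first-order release rate of a protein residue (1 / time).
#' @slot Lmin minimum fragment length (bp) able to hold one Ku; shorter
#'   fragments are irreparable in this model.
#' @slot Lc critical length (bp) at and above which a fragment holds two Ku
#'   simultaneously, one per end.
#' @slot V nuclear volume (arbitrary volume unit); scales both second-order
#'   reactions.
#' @slot includeIrreparable logical; when `TRUE` (comparison mode),
#'   fragments shorter than `Lmin` are admitted into the initial
#'   distribution as inert, never-reacting species.
#' @slot tMax optional simulation time horizon; `Inf` disables it.
#' @name SimParams-class
#' @aliases SimParams-class
#' @exportClass SimParams
setClass("SimParams",
  representation(
    kf = "numeric",
    nE = "numeric",
    kj = "numeric",
    kr = "numeric",
    Lmin = "integer",
    Lc = "integer",
    V = "numeric",
    includeIrreparable = "logical",
    tMax = "numeric"
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  for (nm in c("kf", "kj", "kr")) {
    v <- slot(object, nm)
    if (!.isNumber(v) || v < 0) msg <- c(msg, sprintf("'%s' must be a single non-negative number", nm))
  }
  if (!.isNumber(object@V) || object@V <= 0) msg <- c(msg, "'V' must be a single positive number")
  if (!.isCount(object@nE, 1L)) msg <- c(msg, "'nE' must be a single integer >= 1")
  if (length(object@Lmin) != 1L || is.na(object@Lmin) || object@Lmin < 1L) {
    msg <- c(msg, "'Lmin' must be a single positive integer")
  }
  if (length(object@Lc) != 1L || is.na(object@Lc)) {
    msg <- c(msg, "'Lc' must be a single positive integer")
  } else if (length(object@Lmin) == 1L && !is.na(object@Lmin) && object@Lc <= object@Lmin) {
    msg <- c(msg, "'Lc' must be strictly greater than 'Lmin'")
  }
  if (length(object@includeIrreparable) != 1L || is.na(object@includeIrreparable)) {
    msg <- c(msg, "'includeIrreparable' must be TRUE or FALSE")
  }
  if (length(object@tMax) != 1L || is.na(object@tMax) || object@tMax <= 0) {
    msg <- c(msg, "'tMax' must be a single positive number (Inf allowed)")
  }
  if (length(msg)) msg else TRUE
})

#' FragmentDistribution: an initial fragment-length spectrum
#'
#' A table of distinct fragment lengths (bp) with positive multiplicities,
#' the initial condition of a rejoining simulation. Fragments at least
#' `Lmin` long are "countable" (eligible for Ku binding and therefore for
#' rejoining); shorter ones are irreparable and only admitted in comparison
#' mode.
#'
#' @slot lengths integer vector of distinct fragment lengths (bp).
#' @slot counts integer vector of positive multiplicities, parallel to
#'   `lengths`.
#' @name FragmentDistribution-class
#' @aliases FragmentDistribution-class
#' @exportClass FragmentDistribution
setClass("FragmentDistribution",
  representation(lengths = "integer", counts = "integer")
)

setValidity("FragmentDistribution", function(object) {
  msg <- character()
  if (length(object@lengths) != length(object@counts)) {
    msg <- c(msg, "'lengths' and 'counts' must have equal length")
  }
  if (length(object@lengths) == 0L) msg <- c(msg, "distribution must contain at least one fragment")
  if (anyNA(object@lengths) || any(object@lengths < 1L)) {
    msg <- c(msg, "'lengths' must be positive integers")
  }
  if (anyDuplicated(object@lengths)) msg <- c(msg, "'lengths' must be distinct")
  if (anyNA(object@counts) || any(object@counts < 1L)) {
    msg <- c(msg, "'counts' must be positive integers")
  }
  if (length(msg)) msg else TRUE
})

#' SystemState: the instantaneous state of the reaction network
#'
#' A multiset of fragments with per-end occupancy, plus residue bookkeeping,
#' elapsed time, and event tallies. Ends are coded 0 = FREE, 1 = BOUND,
#' 2 = BLOCKED (`NA` for untracked ends of capacity-0/1 fragments); a
#' blocked end carries the positive id of the residue token blocking it
#' (0 = none). A token present on both ends of a fragment is a double
#' residue (type R, from a short+short join) released by a single event; a
#' token on one end is a single residue (type r, from a short+long join).
#'
#' @slot len integer fragment lengths (bp).
#' @slot cap integer binding-site capacity per fragment (0, 1 or 2).
#' @slot e1,e2 integer end-status codes (see above).
#' @slot t1,t2 integer residue-token ids per end (0 = none).
#' @slot nextToken next unused token id.
#' @slot time elapsed simulation time.
#' @slot nRecruit,nJoin,nRelease event tallies per reaction class.
#' @slot countable0 number of countable (capacity >= 1) fragments at t = 0.
#' @name SystemState-class
#' @aliases SystemState-class
#' @exportClass SystemState
setClass("SystemState",
  representation(
    len = "integer", cap = "integer",
    e1 = "integer", e2 = "integer",
    t1 = "integer", t2 = "integer",
    nextToken = "integer", time = "numeric",
    nRecruit = "integer", nJoin = "integer", nRelease = "integer",
    countable0 = "integer"
  )
)

setValidity("SystemState", function(object) {
  n <- length(object@len)
  msg <- character()
  for (nm in c("cap", "e1", "e2", "t1", "t2")) {
    if (length(slot(object, nm)) != n) msg <- c(msg, sprintf("'%s' length mismatch", nm))
  }
  if (length(msg)) return(msg)
  if (any(object@len < 1L)) msg <- c(msg, "fragment lengths must be positive")
  bad1 <- xor(is.na(object@e1), object@cap < 1L)
  bad2 <- xor(is.na(object@e2), object@cap < 2L)
  if (any(bad1) || any(bad2)) msg <- c(msg, "tracked ends must match capacity")
  blocked1 <- !is.na(object@e1) & object@e1 == .END_BLOCKED
  blocked2 <- !is.na(object@e2) & object@e2 == .END_BLOCKED
  if (any(blocked1 & object@t1 == 0L) || any(blocked2 & object@t2 == 0L)) {
    msg <- c(msg, "every BLOCKED end must carry a residue token")
  }
  if (any(!blocked1 & object@t1 != 0L, na.rm = TRUE) ||
      any(!blocked2 & object@t2 != 0L, na.rm = TRUE)) {
    msg <- c(msg, "residue tokens are only allowed on BLOCKED ends")
  }
  if (length(msg)) msg else TRUE
})

#' Trajectory: a time-stamped event log of one stochastic simulation
#'
#' @slot times strictly increasing event times.
#' @slot kinds event kinds, one of `"recruit"`, `"join"`, `"release"`.
#' @slot counts total fragment count (including irreparables) after each
#'   event; non-increasing.
#' @slot status terminating condition: `"completed"` (countable fragments
#'   merged to one), `"horizon"` (time limit reached) or `"stalled"` (no
#'   reaction channel left with more than one countable fragment).
#' @slot finalState the [SystemState-class] at termination.
#' @slot M0 total initial fragment count; `M0countable` the countable part.
#' @slot seed the seed used (NA if none was fixed).
#' @slot params the [SimParams-class] used.
#' @name Trajectory-class
#' @aliases Trajectory-class
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    times = "numeric", kinds = "character", counts = "integer",
    status = "character", finalState = "SystemState",
    M0 = "integer", M0countable = "integer",
    seed = "integer", params = "SimParams"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@kinds) != n || length(object@counts) != n) {
    msg <- c(msg, "'times', 'kinds' and 'counts' must have equal length")
  }
  if (n > 1L && any(diff(object@times) <= 0)) msg <- c(msg, "'times' must be strictly increasing")
  if (n > 1L && any(diff(object@counts) > 0L)) msg <- c(msg, "'counts' must be non-increasing")
  if (!object@status %in% c("completed", "horizon", "stalled")) {
    msg <- c(msg, "unknown trajectory status")
  }
  if (n > 0L && !all(object@kinds %in% c("recruit", "join", "release"))) {
    msg <- c(msg, "unknown event kind")
  }
  if (length(msg)) msg else TRUE
})

#' EnsembleSummary: rejoining-time statistics over replicate simulations
#'
#' @slot parameter name of the swept parameter (or `"(none)"`).
#' @slot value parameter value at this point.
#' @slot times per-replicate rejoining times.
#' @slot nSamples number of replicates.
#' @name EnsembleSummary-class
#' @aliases EnsembleSummary-class
#' @exportClass EnsembleSummary
setClass("EnsembleSummary",
  representation(
    parameter = "character", value = "numeric",
    times = "numeric", nSamples = "integer"
  )
)

setValidity("EnsembleSummary", function(object) {
  msg <- character()
  if (object@nSamples < 1L) msg <- c(msg, "'nSamples' must be >= 1")
  if (length(object@times) != object@nSamples) msg <- c(msg, "'times' length must equal 'nSamples'")
  if (anyNA(object@times) || any(object@times < 0)) msg <- c(msg, "rejoining times must be non-negative")
  if (length(msg)) msg else TRUE
})

#' KineticsCurve: mean fraction of remaining fragments over time
#'
#' The fraction-remaining curve P(t) = mean over replicates of
#' count(t) / count(0), the model analogue of repair-focus decay curves.
#'
#' @slot time time grid (non-negative, increasing, starting at 0).
#' @slot P mean fraction of remaining fragments at each grid point.
#' @slot nSamples number of replicates averaged.
#' @slot M0 total initial fragment count (including irreparables).
#' @name KineticsCurve-class
#' @aliases KineticsCurve-class
#' @exportClass KineticsCurve
setClass("KineticsCurve",
  representation(time = "numeric", P = "numeric", nSamples = "integer", M0 = "integer")
)

setValidity("KineticsCurve", function(object) {
  msg <- character()
  if (length(object@time) != length(object@P)) msg <- c(msg, "'time' and 'P' must have equal length")
  if (length(object@time) < 1L) msg <- c(msg, "empty time grid")
  if (length(object@time) && object@time[1L] != 0) msg <- c(msg, "time grid must start at 0")
  if (length(object@time) > 1L && any(diff(object@time) <= 0)) msg <- c(msg, "time grid must be increasing")
  if (length(object@P) > 1L && any(diff(object@P) > 1e-12)) msg <- c(msg, "P must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' StateSpace: the exact continuous-time Markov chain of a small system
#'
#' Exhaustive reachable-state enumeration of the rejoining network for a
#' small initial distribution, with canonical state keys (fragment identity
#' and end labelling quotiented out), the transition rate list, and the
#' absorbing set (states with a single countable fragment).
#'
#' @slot keys canonical state encodings.
#' @slot from,to integer indices into `keys` for each transition.
#' @slot rate transition rates, equal to channel propensities.
#' @slot absorbing logical flag per state.
#' @slot initial index of the initial state.
#' @name StateSpace-class
#' @aliases StateSpace-class
#' @exportClass StateSpace
setClass("StateSpace",
  representation(
    keys = "character", from = "integer", to = "integer",
    rate = "numeric", absorbing = "logical", initial = "integer"
  )
)

setValidity("StateSpace", function(object) {
  msg <- character()
  n <- length(object@keys)
  if (length(object@absorbing) != n) msg <- c(msg, "'absorbing' length mismatch")
  m <- length(object@from)
  if (length(object@to) != m || length(object@rate) != m) msg <- c(msg, "transition columns length mismatch")
  if (m && (any(object@from < 1L | object@from > n) || any(object@to < 1L | object@to > n))) {
    msg <- c(msg, "transition indices out of range")
  }
  if (m && any(object@rate <= 0)) msg <- c(msg, "transition rates must be positive")
  if (length(object@initial) != 1L || object@initial < 1L || object@initial > n) {
    msg <- c(msg, "'initial' must index a state")
  }
  if (length(msg)) msg else TRUE
})
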