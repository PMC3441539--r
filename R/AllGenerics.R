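#' @rdname SimParams
#' @export
setGeneric("recruitRate", function(x) standardGeneric("recruitRate"))
#' @rdname SimParams
#' @export
setGeneric("joinRate", function(x) standardGeneric("joinRate"))
#' @rdname SimParams
#' @export
setGeneric("releaseRate", function(x) standardGeneric("releaseRate"))
#' @rdname SimParams
#' @export
setGeneric("releaseRate<-", function(x, value) standardGeneric("releaseRate<-"))
#' @rdname SimParams
#' @export
setGeneric("proteinCopies", function(x) standardGeneric("proteinCopies"))
#' @rdname SimParams
#' @export
setGeneric("minBindingLength", function(x) standardGeneric("minBindingLength"))
#' @rdname SimParams
#' @export
setGeneric("criticalLength", function(x) standardGeneric("criticalLength"))
#' @rdname SimParams
#' @export
setGeneric("nuclearVolume", function(x) standardGeneric("nuclearVolume"))
#' @rdname SimParams
#' @export
setGeneric("nuclearVolume<-", function(x, value) standardGeneric("nuclearVolume<-"))
#' @rdname SimParams
#' @export
setGeneric("timeHorizon", function(x) standardGeneric("timeHorizon"))

#' Total number of fragments
#'
#' `totalFragments` counts all fragments (M0 for a distribution);
#' `countableFragments` counts only fragments long enough to bind Ku
#' (length >= `Lmin`), i.e. those that participate in rejoining;
#' `totalLength` sums fragment lengths in bp; `meanLength` is their mean.
#'
#' @param x a [FragmentDistribution-class] or [SystemState-class].
#' @param params a [SimParams-class] supplying `Lmin` where needed.
#' @param ... passed to methods.
#' @return A single number.
#' @export
setGeneric("totalFragments", function(x, ...) standardGeneric("totalFragments"))
#' @rdname totalFragments
#' @export
setGeneric("countableFragments", function(x, ...) standardGeneric("countableFragments"))
#' @rdname totalFragments
#' @export
setGeneric("totalLength", function(x, ...) standardGeneric("totalLength"))
#' @rdname totalFragments
#' @export
setGeneric("meanLength", function(x, ...) standardGeneric("meanLength"))

#' Fraction of short fragments in a distribution
#'
#' The fraction of fragments shorter than the critical length `Lc` (the
#' "short" class of the radiation-quality presets). Irreparable fragments
#' (below `Lmin`) count as short.
#'
#' @param x a [FragmentDistribution-class].
#' @param params a [SimParams-class].
#' @return A fraction in `[0, 1]`.
#' @export
setGeneric("shortFraction", function(x, params) standardGeneric("shortFraction"))

#' Fragment table of a system state
#'
#' @param x a [SystemState-class].
#' @return A `data.frame` with one row per fragment: length, capacity, end
#'   statuses and residue-token ids.
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' Rejoining time of a completed trajectory
#'
#' The elapsed time from the initial countable fragments down to a single
#' fragment: the timestamp of the last join event. Release events occurring
#' after the final join do not extend it (termination is defined on
#' fragment count alone). For a trajectory that did not complete, the value
#' is undefined and `NA` is returned with a warning.
#'
#' @param x a [Trajectory-class].
#' @return A single non-negative time, or `NA`.
#' @export
setGeneric("rejoiningTime", function(x) standardGeneric("rejoiningTime"))

#' @rdname Trajectory-utils
#' @export
setGeneric("terminationStatus", function(x) standardGeneric("terminationStatus"))
#' @rdname Trajectory-utils
#' @export
setGeneric("finalState", function(x) standardGeneric("finalState"))
#' @rdname Trajectory-utils
#' @export
setGeneric("eventCounts", function(x) standardGeneric("eventCounts"))

#' @rdname EnsembleSummary-utils
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))
#' @rdname EnsembleSummary-utils
#' @export
setGeneric("meanTime", function(x) standardGeneric("meanTime"))
#' @rdname EnsembleSummary-utils
#' @export
setGeneric("standardError", function(x) standardGeneric("standardError"))
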