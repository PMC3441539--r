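#' Rejoining-time statistics over replicate simulations
#'
#' Runs `nSamples` independent simulations of the same initial distribution
#' (replicate `i` seeded with `deriveSeed(masterSeed, i)`) and collects the
#' per-sample rejoining times. The across-sample mean is the mean rejoining
#' time; minimum and maximum delimit the fluctuation bar.
#'
#' @param dist a [FragmentDistribution-class].
#' @param params a [SimParams-class].
#' @param nSamples number of replicates (>= 1).
#' @param masterSeed master seed for the replicate seed stream.
#' @param parameter,value optional labels recorded in the summary (used by
#'   [parameterSweep()]).
#' @return An [EnsembleSummary-class].
#' @examples
#' s <- replicateTimes(fixedLengthDistribution(3, 100), SimParams(),
#'   nSamples = 50, masterSeed = 1)
#' meanTime(s)
#' @export
replicateTimes <- function(dist, params = SimParams(), nSamples = 150L,
                           masterSeed = 1L, parameter = "(none)", value = NA_real_) {
  stopifnot(is(dist, "FragmentDistribution"))
  if (!.isCount(nSamples)) stop("'nSamples' must be a positive integer", call. = FALSE)
  times <- vapply(seq_len(nSamples), function(i) {
    tr <- simulateRejoining(dist, params, seed = deriveSeed(masterSeed, i))
    if (tr@status != "completed") {
      stop(sprintf("replicate %d terminated '%s' instead of completing; %s",
        i, tr@status,
        if (tr@status == "horizon") "raise tMax" else "this signals a model bug"),
        call. = FALSE)
    }
    rejoiningTime(tr)
  }, numeric(1L))
  new("EnsembleSummary",
    parameter = parameter, value = as.numeric(value),
    times = times, nSamples = as.integer(nSamples)
  )
}

#' Ensemble summary accessors
#'
#' @param x an [EnsembleSummary-class].
#' @name EnsembleSummary-utils
NULL

#' @rdname EnsembleSummary-utils
#' @export
setMethod("sampleTimes", "EnsembleSummary", function(x) x@times)
#' @rdname EnsembleSummary-utils
#' @export
setMethod("meanTime", "EnsembleSummary", function(x) mean(x@times))
#' @rdname EnsembleSummary-utils
#' @export
setMethod("standardError", "EnsembleSummary", function(x) {
  if (x@nSamples < 2L) return(0)
  stats::sd(x@times) / sqrt(x@nSamples)
})

#' @describeIn EnsembleSummary-utils one-row `data.frame`
#'   (`parameter`, `value`, `n_samples`, `mean`, `min`, `max`, `se`).
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.EnsembleSummary <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    parameter = x@parameter, value = x@value, n_samples = x@nSamples,
    mean = mean(x@times), min = min(x@times), max = max(x@times),
    se = standardError(x)
  )
}

setMethod("show", "EnsembleSummary", function(object) {
  cat(sprintf(
    "EnsembleSummary (%s = %g): n = %d, mean rejoining time %.4g (min %.4g, max %.4g, se %.3g)\n",
    object@parameter, object@value, object@nSamples,
    mean(object@times), min(object@times), max(object@times),
    standardError(object)
  ))
  invisible(NULL)
})

#' Mean fraction-remaining kinetics
#'
#' Averages the fragment-count decay of `nSamples` replicate simulations on
#' a fixed time grid: per replicate the fragment count at `t` is the count
#' after the last event at or before `t` (irreparable fragments included),
#' and `P(t)` is the mean of `count(t) / count(0)`. With irreparable
#' fragments present the curve plateaus at or above their initial fraction
#' — the model analogue of residual repair foci.
#'
#' @param dist a [FragmentDistribution-class].
#' @param params a [SimParams-class].
#' @param nSamples number of replicates.
#' @param timeGrid increasing grid starting at 0.
#' @param masterSeed master seed.
#' @return A [KineticsCurve-class].
#' @export
meanKinetics <- function(dist, params = SimParams(), nSamples = 200L,
                         timeGrid = seq(0, 50, by = 0.5), masterSeed = 1L) {
  stopifnot(is(dist, "FragmentDistribution"))
  if (!length(timeGrid)) stop("'timeGrid' must be non-empty", call. = FALSE)
  timeGrid <- sort(unique(c(0, as.numeric(timeGrid))))
  horizon <- max(timeGrid)
  M0 <- totalFragments(dist)
  acc <- numeric(length(timeGrid))
  for (i in seq_len(nSamples)) {
    tr <- simulateRejoining(dist, params, seed = deriveSeed(masterSeed, i),
      tMax = max(horizon, timeHorizon(params)))
    counts <- c(M0, tr@counts)
    idx <- findInterval(timeGrid, tr@times) + 1L
    acc <- acc + counts[idx]
  }
  new("KineticsCurve",
    time = timeGrid, P = acc / (nSamples * M0),
    nSamples = as.integer(nSamples), M0 = as.integer(M0)
  )
}

#' @describeIn meanKinetics curve as a `data.frame` (`time`, `P_mean`).
#' @param x a [KineticsCurve-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.KineticsCurve <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time = x@time, P_mean = x@P)
}

setMethod("show", "KineticsCurve", function(object) {
  cat(sprintf(
    "KineticsCurve: %d grid points on [0, %g], %d samples, M0 = %d; P(end) = %.3f\n",
    length(object@time), max(object@time), object@nSamples, object@M0,
    object@P[length(object@P)]
  ))
  invisible(NULL)
})

#' Sweep one model parameter and summarize rejoining times
#'
#' For each value of the swept parameter, runs [replicateTimes()] with all
#' other settings held fixed. Supported parameters: `"V"` (nuclear volume),
#' `"k_r"` (residue release rate), `"M0"` (initial fragment number, using a
#' fixed-length distribution of length `length`), and `"fixed_length_n"`
#' (common initial length, with `M0` fragments). Each sweep point `p` uses
#' master seed `deriveSeed(masterSeed, 7919 * p)` so points are independent
#' and the whole table is reproducible.
#'
#' @param params base [SimParams-class].
#' @param parameter one of `"V"`, `"k_r"`, `"M0"`, `"fixed_length_n"`.
#' @param values sweep values (non-empty).
#' @param nSamples replicates per point.
#' @param masterSeed master seed.
#' @param dist base [FragmentDistribution-class] for `"V"`/`"k_r"` sweeps;
#'   defaults to a fixed-length distribution of `M0` fragments of `length`.
#' @param M0,length fixed-length distribution settings.
#' @return A `data.frame` sorted by value with columns `parameter`,
#'   `value`, `n_samples`, `mean`, `min`, `max`, `se`.
#' @export
parameterSweep <- function(params = SimParams(), parameter, values,
                           nSamples = 150L, masterSeed = 1L,
                           dist = NULL, M0 = 20L, length = 100L) {
  if (!is.character(parameter) || length(parameter) != 1L ||
      !parameter %in% c("V", "k_r", "M0", "fixed_length_n")) {
    stop("'parameter' must be one of \"V\", \"k_r\", \"M0\", \"fixed_length_n\"",
      call. = FALSE)
  }
  if (!length(values)) stop("'values' must be non-empty", call. = FALSE)
  values <- sort(as.numeric(values))
  if (is.null(dist) && parameter %in% c("V", "k_r")) {
    dist <- fixedLengthDistribution(M0, length, params)
  }
  rows <- lapply(seq_along(values), function(p) {
    v <- values[p]
    pointSeed <- deriveSeed(masterSeed, 7919 * p)
    pars <- params
    d <- dist
    if (parameter == "V") {
      nuclearVolume(pars) <- v
    } else if (parameter == "k_r") {
      releaseRate(pars) <- v
    } else if (parameter == "M0") {
      d <- fixedLengthDistribution(as.integer(v), length, pars)
    } else {
      d <- fixedLengthDistribution(M0, as.integer(v), pars)
    }
    as.data.frame(replicateTimes(d, pars, nSamples, pointSeed,
      parameter = parameter, value = v))
  })
  do.call(rbind, rows)
}

#' Mean rejoining time over the short-fraction simplex
#'
#' For each feasible grid point `(q1, q2)` (with `q1 + q2 <= 1`), samples
#' `nDistributions` fraction-pair distributions, summarizes each by
#' [replicateTimes()], and averages the per-distribution mean rejoining
#' times: `T(q1, q2)` is a mean of means. Infeasible grid points are
#' skipped with a warning.
#'
#' @param params a [SimParams-class].
#' @param q1Grid,q2Grid fraction grids.
#' @param M0 fragments per sampled distribution.
#' @param nDistributions distributions per grid point.
#' @param nSamples replicates per distribution.
#' @param masterSeed master seed.
#' @param longMax upper bound of the long length band (bp).
#' @return A `data.frame` with columns `q1`, `q2`, `mean_time`,
#'   `n_distributions`, `n_samples`.
#' @export
fractionSurface <- function(params = SimParams(), q1Grid = seq(0, 0.8, by = 0.2),
                            q2Grid = seq(0, 0.8, by = 0.2), M0 = 20L,
                            nDistributions = 10L, nSamples = 30L,
                            masterSeed = 1L, longMax = 3000L) {
  grid <- expand.grid(q1 = as.numeric(q1Grid), q2 = as.numeric(q2Grid))
  keep <- grid$q1 + grid$q2 <= 1 + 1e-12
  if (!all(keep)) {
    warning(sprintf("skipping %d infeasible grid point(s) with q1 + q2 > 1",
      sum(!keep)))
  }
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) stop("no feasible grid points", call. = FALSE)
  res <- vapply(seq_len(nrow(grid)), function(g) {
    pointSeed <- deriveSeed(masterSeed, 104729 * g)
    means <- vapply(seq_len(nDistributions), function(d) {
      dSeed <- deriveSeed(pointSeed, d)
      dd <- fractionPairDistribution(M0, grid$q1[g], grid$q2[g],
        seed = dSeed, params = params, longMax = longMax)
      meanTime(replicateTimes(dd, params, nSamples, deriveSeed(dSeed, 999999)))
    }, numeric(1L))
    mean(means)
  }, numeric(1L))
  data.frame(
    q1 = grid$q1, q2 = grid$q2, mean_time = res,
    n_distributions = as.integer(nDistributions),
    n_samples = as.integer(nSamples), row.names = NULL
  )
}

#' @describeIn meanKinetics base-graphics plot of a kinetics curve
#'   (time vs mean fraction of remaining fragments).
#' @param y ignored.
#' @export
setMethod("plot", signature("KineticsCurve", "missing"), function(x, y, ...) {
  graphics::plot(x@time, x@P, type = "l", xlab = "time",
    ylab = "mean fraction of remaining fragments P(t)",
    ylim = c(0, 1), ...)
  invisible(NULL)
})

#' @describeIn EnsembleSummary-utils plot rejoining-time fluctuation bar
#'   (min-mean-max) of a summary.
#' @param y ignored.
#' @export
setMethod("plot", signature("EnsembleSummary", "missing"), function(x, y, ...) {
  m <- mean(x@times)
  graphics::plot(x@value, m, ylim = range(x@times), xlab = x@parameter,
    ylab = "rejoining time", pch = 19, ...)
  graphics::arrows(x@value, min(x@times), x@value, max(x@times),
    angle = 90, code = 3, length = 0.05)
  invisible(NULL)
})
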