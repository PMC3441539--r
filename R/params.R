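#' Construct a parameter set for the rejoining model
#'
#' All defaults are dimensionless model units. The length thresholds follow
#' the biochemistry of the Ku heterodimer: roughly 20 bp of double-stranded
#' DNA are needed for one Ku to bind efficiently, and a 42 bp duplex can
#' hold two Ku simultaneously, one at each end. Rate constants are unit
#' rates by default because only their ratios (through `kf*nE/V`, `kj/V`,
#' `kr`) shape the kinetics; absolute values rescale time.
#'
#' @param kf bimolecular recruitment rate constant (volume/time).
#' @param nE repair-protein copy number (constant; protein is abundant).
#' @param kj bimolecular joining rate constant (volume/time).
#' @param kr first-order residue release rate (1/time).
#' @param Lmin minimum length for Ku binding (bp).
#' @param Lc critical length for two simultaneous Ku (bp).
#' @param V nuclear volume (arbitrary unit).
#' @param includeIrreparable admit fragments below `Lmin` as inert species
#'   (comparison mode).
#' @param tMax simulation time horizon (`Inf` = run to completion).
#' @return A validated [SimParams-class] object.
#' @examples
#' p <- SimParams()
#' siteCapacity(c(19, 20, 41, 42), p)
#' @export
SimParams <- function(kf = 1, nE = 1L, kj = 1, kr = 1,
                      Lmin = 20L, Lc = 42L, V = 1,
                      includeIrreparable = FALSE, tMax = Inf) {
  new("SimParams",
    kf = as.numeric(kf), nE = as.numeric(nE), kj = as.numeric(kj),
    kr = as.numeric(kr), Lmin = as.integer(Lmin), Lc = as.integer(Lc),
    V = as.numeric(V), includeIrreparable = as.logical(includeIrreparable),
    tMax = as.numeric(tMax)
  )
}

#' @describeIn SimParams recruitment rate constant `kf`.
#' @param x,value a `SimParams` object / replacement value.
#' @export
setMethod("recruitRate", "SimParams", function(x) x@kf)
#' @describeIn SimParams joining rate constant `kj`.
#' @export
setMethod("joinRate", "SimParams", function(x) x@kj)
#' @describeIn SimParams residue release rate `kr`.
#' @export
setMethod("releaseRate", "SimParams", function(x) x@kr)
#' @describeIn SimParams set `kr`.
#' @export
setMethod("releaseRate<-", "SimParams", function(x, value) {
  x@kr <- as.numeric(value)
  validObject(x)
  x
})
#' @describeIn SimParams repair-protein copy number `nE`.
#' @export
setMethod("proteinCopies", "SimParams", function(x) x@nE)
#' @describeIn SimParams minimum binding length `Lmin` (bp).
#' @export
setMethod("minBindingLength", "SimParams", function(x) x@Lmin)
#' @describeIn SimParams critical length `Lc` (bp).
#' @export
setMethod("criticalLength", "SimParams", function(x) x@Lc)
#' @describeIn SimParams nuclear volume `V`.
#' @export
setMethod("nuclearVolume", "SimParams", function(x) x@V)
#' @describeIn SimParams set `V`.
#' @export
setMethod("nuclearVolume<-", "SimParams", function(x, value) {
  x@V <- as.numeric(value)
  validObject(x)
  x
})
#' @describeIn SimParams time horizon `tMax`.
#' @export
setMethod("timeHorizon", "SimParams", function(x) x@tMax)

setMethod("show", "SimParams", function(object) {
  cat("SimParams (Ku-dependent NHEJ rejoining model)\n")
  cat(sprintf("  recruitment: kf = %g, nE = %g  (per free end: kf*nE/V = %g)\n",
    object@kf, object@nE, object@kf * object@nE / object@V))
  cat(sprintf("  joining:     kj = %g            (per bound-end pair: kj/V = %g)\n",
    object@kj, object@kj / object@V))
  cat(sprintf("  release:     kr = %g\n", object@kr))
  cat(sprintf("  thresholds:  Lmin = %d bp, Lc = %d bp; volume V = %g\n",
    object@Lmin, object@Lc, object@V))
  cat(sprintf("  mode: %s; tMax = %g\n",
    if (object@includeIrreparable) "comparison (irreparables kept)" else "default",
    object@tMax))
  invisible(NULL)
})
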