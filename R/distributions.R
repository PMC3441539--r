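#' Construct a fragment-length distribution
#'
#' Builds a validated [FragmentDistribution-class] from parallel vectors of
#' lengths and counts (duplicated lengths are aggregated) or from raw
#' per-fragment lengths via `counts = NULL`.
#'
#' @param lengths fragment lengths in bp.
#' @param counts multiplicities, parallel to `lengths`; `NULL` treats
#'   `lengths` as one entry per fragment.
#' @return A [FragmentDistribution-class].
#' @examples
#' FragmentDistribution(c(30, 100), c(2, 5))
#' @export
FragmentDistribution <- function(lengths, counts = NULL) {
  lengths <- .assertWholeLengths(lengths)
  if (is.null(counts)) {
    tab <- table(lengths)
    lengths <- as.integer(names(tab))
    counts <- as.integer(tab)
  } else {
    if (!is.numeric(counts) || length(counts) != length(lengths) || anyNA(counts) ||
        any(counts != floor(counts)) || any(counts < 1)) {
      stop("'counts' must be positive integers parallel to 'lengths'", call. = FALSE)
    }
    counts <- as.integer(counts)
    if (anyDuplicated(lengths)) {
      agg <- rowsum(counts, lengths)
      lengths <- as.integer(rownames(agg))
      counts <- as.integer(agg[, 1L])
    }
  }
  o <- order(lengths)
  new("FragmentDistribution", lengths = lengths[o], counts = counts[o])
}

#' @describeIn totalFragments total fragment count M0 of a distribution.
#' @export
setMethod("totalFragments", "FragmentDistribution", function(x, ...) sum(x@counts))
#' @describeIn totalFragments countable fragments (length >= `Lmin`) of a
#'   distribution.
#' @export
setMethod("countableFragments", "FragmentDistribution", function(x, params = SimParams(), ...) {
  sum(x@counts[x@lengths >= params@Lmin])
})
#' @describeIn totalFragments total DNA length (bp) of a distribution.
#' @export
setMethod("totalLength", "FragmentDistribution", function(x, ...) {
  sum(as.numeric(x@lengths) * x@counts)
})
#' @describeIn totalFragments mean fragment length (bp) of a distribution.
#' @export
setMethod("meanLength", "FragmentDistribution", function(x, ...) {
  totalLength(x) / totalFragments(x)
})

#' @describeIn shortFraction fraction of fragments below `Lc`.
#' @export
setMethod("shortFraction", signature("FragmentDistribution", "SimParams"), function(x, params) {
  sum(x@counts[x@lengths < params@Lc]) / sum(x@counts)
})

#' Fragment lengths table accessors
#'
#' @param dist a [FragmentDistribution-class].
#' @return `distributionTable` returns a two-column `data.frame`
#'   (`length`, `count`).
#' @export
distributionTable <- function(dist) {
  stopifnot(is(dist, "FragmentDistribution"))
  data.frame(length = dist@lengths, count = dist@counts)
}

setMethod("show", "FragmentDistribution", function(object) {
  cat(sprintf(
    "FragmentDistribution: %d fragment(s) over %d length(s); mean length %.1f bp\n",
    totalFragments(object), length(object@lengths), meanLength(object)
  ))
  tab <- distributionTable(object)
  if (nrow(tab) <= 12L) print(tab) else {
    print(utils::head(tab, 6L))
    cat(sprintf("  ... %d more lengths\n", nrow(tab) - 6L))
  }
  invisible(NULL)
})

## ---- generators ----------------------------------------------------------

#' Fixed-length initial distribution
#'
#' `M0` fragments, all of the same length `n` — the configuration used to
#' study the mean rejoining time as a function of a single initial length.
#'
#' @param M0 number of fragments (>= 1).
#' @param n common fragment length (bp).
#' @param params a [SimParams-class]; in default mode `n < Lmin` is
#'   rejected.
#' @return A [FragmentDistribution-class].
#' @examples
#' fixedLengthDistribution(10, 100)
#' @export
fixedLengthDistribution <- function(M0, n, params = SimParams()) {
  if (!.isCount(M0)) stop("'M0' must be a positive integer", call. = FALSE)
  n <- .assertWholeLengths(n)
  if (!params@includeIrreparable && n < params@Lmin) {
    stop(sprintf("length %d is below Lmin = %d and cannot recruit Ku", n, params@Lmin),
      call. = FALSE)
  }
  new("FragmentDistribution", lengths = n, counts = as.integer(M0))
}

#' Uniform-random initial distribution
#'
#' Draws `kSpecies` distinct fragment lengths uniformly (without
#' replacement) from an integer range, and a uniform count for each.
#'
#' @param kSpecies number of distinct lengths.
#' @param lengthRange integer range `c(lo, hi)` for lengths (bp).
#' @param countRange integer range `c(lo, hi)` for per-length counts.
#' @param seed RNG seed (`NULL` = current stream).
#' @param params a [SimParams-class] for mode validation.
#' @return A [FragmentDistribution-class].
#' @export
uniformRandomDistribution <- function(kSpecies, lengthRange = c(20L, 2000L),
                                      countRange = c(1L, 10L), seed = NULL,
                                      params = SimParams()) {
  if (!.isCount(kSpecies)) stop("'kSpecies' must be a positive integer", call. = FALSE)
  lengthRange <- .assertWholeLengths(lengthRange)
  if (length(lengthRange) != 2L || lengthRange[2L] < lengthRange[1L]) {
    stop("'lengthRange' must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  nAvail <- lengthRange[2L] - lengthRange[1L] + 1L
  if (kSpecies > nAvail) {
    stop(sprintf("'lengthRange' holds only %d distinct lengths < kSpecies = %d",
      nAvail, kSpecies), call. = FALSE)
  }
  if (!is.numeric(countRange) || length(countRange) != 2L || any(countRange < 1) ||
      countRange[2L] < countRange[1L]) {
    stop("'countRange' must be c(lo, hi) with 1 <= lo <= hi", call. = FALSE)
  }
  .withSeed(seed, {
    lens <- .sampleRange(lengthRange[1L], lengthRange[2L], kSpecies, replace = FALSE)
    cnts <- .sampleRange(as.integer(countRange[1L]), as.integer(countRange[2L]), kSpecies)
    dist <- FragmentDistribution(lens, cnts)
    if (!params@includeIrreparable && any(dist@lengths < params@Lmin)) {
      stop(sprintf("'lengthRange' includes lengths below Lmin = %d in default mode",
        params@Lmin), call. = FALSE)
    }
    dist
  })
}

#' Two-class (radiation-quality) initial distribution
#'
#' Splits `M0` fragments into a short class (below the critical length
#' `Lc`) and a long class (at or above `Lc`). The class split is a
#' deterministic apportionment — exactly `round(M0 * pShort)` short
#' fragments, remainder long — so preset fractions are exact; only lengths
#' within each class are sampled uniformly. The presets encode the damage
#' spectra of 1 Gy exposures: high-LET Fe ions yield 30% short fragments,
#' low-LET gamma rays 3%.
#'
#' @param M0 total fragment count.
#' @param pShort fraction of short fragments in `[0, 1]`.
#' @param shortRange integer length range for shorts, within
#'   `[Lmin, Lc - 1]`.
#' @param longRange integer length range for longs, within `[Lc, Inf)`.
#' @param seed RNG seed.
#' @param params a [SimParams-class].
#' @return A [FragmentDistribution-class].
#' @examples
#' d <- radiationPreset("fe_ion", M0 = 200, seed = 1)
#' shortFraction(d, SimParams())
#' @export
twoClassDistribution <- function(M0, pShort, shortRange = NULL, longRange = NULL,
                                 seed = NULL, params = SimParams()) {
  if (!.isCount(M0)) stop("'M0' must be a positive integer", call. = FALSE)
  if (!.isNumber(pShort) || pShort < 0 || pShort > 1) {
    stop("'pShort' must be a fraction in [0, 1]", call. = FALSE)
  }
  if (is.null(shortRange)) shortRange <- c(params@Lmin, params@Lc - 1L)
  if (is.null(longRange)) longRange <- c(params@Lc, 3000L)
  shortRange <- .assertWholeLengths(shortRange)
  longRange <- .assertWholeLengths(longRange)
  if (shortRange[1L] < params@Lmin || shortRange[2L] >= params@Lc) {
    stop(sprintf("'shortRange' must lie within [Lmin, Lc) = [%d, %d)",
      params@Lmin, params@Lc), call. = FALSE)
  }
  if (longRange[1L] < params@Lc) {
    stop(sprintf("'longRange' must lie within [Lc, Inf) = [%d, Inf)", params@Lc),
      call. = FALSE)
  }
  nShort <- as.integer(round(M0 * pShort))
  nLong <- as.integer(M0) - nShort
  .withSeed(seed, {
    lens <- c(
      if (nShort > 0L) .sampleRange(shortRange[1L], shortRange[2L], nShort),
      if (nLong > 0L) .sampleRange(longRange[1L], longRange[2L], nLong)
    )
    FragmentDistribution(lens)
  })
}

#' @describeIn twoClassDistribution radiation-quality presets:
#'   `"fe_ion"` (1 Gy Fe ions, 30% short / 70% long) and `"gamma"`
#'   (1 Gy gamma rays, 3% short / 97% long).
#' @param preset `"fe_ion"` or `"gamma"`.
#' @export
radiationPreset <- function(preset = c("fe_ion", "gamma"), M0 = 200L, seed = NULL,
                            params = SimParams()) {
  preset <- match.arg(preset)
  pShort <- switch(preset, fe_ion = 0.30, gamma = 0.03)
  twoClassDistribution(M0, pShort, seed = seed, params = params)
}

#' Fraction-pair initial distribution
#'
#' Apportions `M0` fragments over three length bands: a fraction `q1` of
#' very short fragments in `[Lmin, ceiling(Lc/2))` — whose pairwise joins
#' still fall short of `Lc` — a fraction `q2` in `[ceiling(Lc/2), Lc)`, and
#' the remainder long, in `[Lc, longMax]`. Class counts are deterministic
#' (`round`, remainder to the long class); lengths within each band are
#' uniform.
#'
#' @param M0 total fragment count.
#' @param q1,q2 short-band fractions, `q1 + q2 <= 1`.
#' @param seed RNG seed.
#' @param params a [SimParams-class].
#' @param longMax upper length bound (bp) of the long band.
#' @return A [FragmentDistribution-class].
#' @export
fractionPairDistribution <- function(M0, q1, q2, seed = NULL, params = SimParams(),
                                     longMax = 3000L) {
  if (!.isCount(M0)) stop("'M0' must be a positive integer", call. = FALSE)
  if (!.isNumber(q1) || !.isNumber(q2) || q1 < 0 || q2 < 0 || q1 + q2 > 1 + 1e-12) {
    stop("'q1' and 'q2' must be non-negative with q1 + q2 <= 1", call. = FALSE)
  }
  half <- as.integer(ceiling(params@Lc / 2))
  if (half <= params@Lmin) {
    stop("degenerate bands: ceiling(Lc/2) must exceed Lmin", call. = FALSE)
  }
  n1 <- as.integer(round(M0 * q1))
  n2 <- min(as.integer(round(M0 * q2)), as.integer(M0) - n1)
  nLong <- as.integer(M0) - n1 - n2
  .withSeed(seed, {
    lens <- c(
      if (n1 > 0L) .sampleRange(params@Lmin, half - 1L, n1),
      if (n2 > 0L) .sampleRange(half, params@Lc - 1L, n2),
      if (nLong > 0L) .sampleRange(params@Lc, as.integer(longMax), nLong)
    )
    FragmentDistribution(lens)
  })
}

#' Append irreparable (sub-minimum) fragments
#'
#' Adds capacity-0 fragments — shorter than `Lmin`, never able to bind Ku —
#' so that they make up fraction `pIrr` of the resulting total. Used in
#' comparison mode, where unrejoined short fragments explain the plateau of
#' repair-focus decay curves. The count added is
#' `round(M0 * pIrr / (1 - pIrr))`, a deterministic apportionment.
#'
#' @param dist countable-fragment [FragmentDistribution-class].
#' @param pIrr target irreparable fraction of the new total, in `[0, 1)`.
#' @param irrRange integer length range within `[1, Lmin)`.
#' @param seed RNG seed.
#' @param params a [SimParams-class]; must have `includeIrreparable = TRUE`.
#' @return A [FragmentDistribution-class] including the inert fragments.
#' @export
addIrreparable <- function(dist, pIrr, irrRange = NULL, seed = NULL,
                           params = SimParams(includeIrreparable = TRUE)) {
  stopifnot(is(dist, "FragmentDistribution"))
  if (!params@includeIrreparable) {
    stop("irreparable fragments require comparison mode ('includeIrreparable = TRUE')",
      call. = FALSE)
  }
  if (!.isNumber(pIrr) || pIrr < 0 || pIrr >= 1) {
    stop("'pIrr' must be a fraction in [0, 1)", call. = FALSE)
  }
  if (pIrr == 0) return(dist)
  if (is.null(irrRange)) irrRange <- c(max(1L, params@Lmin - 10L), params@Lmin - 1L)
  irrRange <- .assertWholeLengths(irrRange)
  if (irrRange[2L] >= params@Lmin) {
    stop(sprintf("'irrRange' must lie within [1, Lmin) = [1, %d)", params@Lmin),
      call. = FALSE)
  }
  M0 <- totalFragments(dist)
  nIrr <- as.integer(round(M0 * pIrr / (1 - pIrr)))
  if (nIrr == 0L) return(dist)
  .withSeed(seed, {
    lens <- .sampleRange(irrRange[1L], irrRange[2L], nIrr)
    FragmentDistribution(
      c(rep(dist@lengths, dist@counts), lens)
    )
  })
}

## ---- file format ---------------------------------------------------------

#' Read / write a fragment distribution as tab-separated text
#'
#' The on-disk format is a two-column TSV with header line
#' `length<TAB>count` and integer cells; identical for read and write.
#'
#' @param path file path.
#' @param dist a [FragmentDistribution-class].
#' @return `readFragmentDistribution` returns a
#'   [FragmentDistribution-class]; `writeFragmentDistribution` its `dist`
#'   argument, invisibly.
#' @export
readFragmentDistribution <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
    colClasses = "integer")
  if (!identical(names(tab), c("length", "count"))) {
    stop(sprintf("'%s': expected header 'length<TAB>count', found '%s'",
      path, paste(names(tab), collapse = "\t")), call. = FALSE)
  }
  FragmentDistribution(tab$length, tab$count)
}

#' @rdname readFragmentDistribution
#' @export
writeFragmentDistribution <- function(dist, path) {
  stopifnot(is(dist, "FragmentDistribution"))
  write.table(distributionTable(dist), path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE)
  invisible(dist)
}
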