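#' @import methods
#' @importFrom stats rexp runif setNames
#' @importFrom utils read.delim write.table
#' @importFrom graphics plot arrows
#' @importFrom yaml read_yaml write_yaml
#' @importFrom optparse OptionParser make_option parse_args
NULL

# End-status codes used throughout the internal state representation.
.END_FREE <- 0L
.END_BOUND <- 1L
.END_BLOCKED <- 2L

.END_LABELS <- c("FREE", "BOUND", "BLOCKED")

.endLabel <- function(code) {
  out <- rep(NA_character_, length(code))
  ok <- !is.na(code)
  out[ok] <- .END_LABELS[code[ok] + 1L]
  out
}

# Uniform integer draws from [lo, hi], safe against the base::sample()
# scalar-x convention when the range collapses to a single value.
.sampleRange <- function(lo, hi, n, replace = TRUE) {
  lo + sample.int(hi - lo + 1L, n, replace = replace) - 1L
}

.isCount <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= min
}

.isNumber <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x)
}

.assertWholeLengths <- function(length) {
  if (!is.numeric(length) || length(length) == 0L || anyNA(length) ||
      any(length != floor(length)) || any(length < 1)) {
    stop("fragment lengths must be positive integers", call. = FALSE)
  }
  as.integer(length)
}

#' Derive a replicate seed from a master seed
#'
#' Ensemble experiments run many independent simulations from one
#' `masterSeed`. Replicate `i` uses the seed returned here, a fixed affine
#' congruential mix modulo the Mersenne prime 2^31 - 1, so that the stream
#' assigned to a replicate does not depend on how many replicates are run.
#'
#' @param masterSeed single non-negative integer (below 2^31).
#' @param i replicate (or sub-stream) index, a non-negative integer.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @examples
#' deriveSeed(1L, 1:3)
#' @export
deriveSeed <- function(masterSeed, i) {
  if (!is.numeric(masterSeed) || length(masterSeed) != 1L || is.na(masterSeed)) {
    stop("'masterSeed' must be a single integer", call. = FALSE)
  }
  # 1000003 * i + masterSeed stays well below 2^53 for any realistic i,
  # so the double-precision modulo is exact.
  as.integer((as.numeric(masterSeed) + as.numeric(i) * 1000003) %% 2147483646) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. `seed = NULL` uses (and advances) the
# current RNG stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer or NULL", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}
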