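## Configuration and command-line interface.
##
## The canonical configuration dialect is YAML with four top-level maps:
## `params` (rate constants and thresholds), `generator` (initial
## distribution), `experiment` (what to run), `output` (paths). Every run
## echoes its fully-resolved effective configuration next to its outputs,
## so any table is regenerable from the echo alone.

.CONFIG_DEFAULTS <- list(
  params = list(
    k_f = 1, n_E = 1L, k_j = 1, k_r = 1, L_min = 20L, L_c = 42L, V = 1,
    include_irreparable = FALSE, t_max = Inf
  ),
  generator = list(name = "fixed_length", M0 = 20L, n = 100L),
  experiment = list(kind = "simulate", n_samples = 150L, master_seed = 1L),
  output = list(prefix = "nhejsim_run")
)

.GENERATOR_FIELDS <- list(
  fixed_length = c("M0", "n"),
  uniform_random = c("k_species", "length_range", "count_range"),
  two_class = c("M0", "p_short", "short_range", "long_range"),
  preset = c("preset", "M0"),
  fraction_pair = c("M0", "q1", "q2", "long_max"),
  file = c("path")
)

.EXPERIMENT_KINDS <- c("simulate", "ensemble", "sweep", "surface", "kinetics", "oracle")

.validateConfig <- function(cfg) {
  known <- names(.CONFIG_DEFAULTS)
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop(sprintf("unknown configuration section(s): %s", paste(extra, collapse = ", ")),
      call. = FALSE)
  }
  out <- .CONFIG_DEFAULTS
  for (sec in names(cfg)) {
    if (!is.list(cfg[[sec]])) {
      stop(sprintf("configuration section '%s' must be a mapping", sec), call. = FALSE)
    }
    for (key in names(cfg[[sec]])) {
      out[[sec]][[key]] <- cfg[[sec]][[key]]
    }
  }
  p <- out$params
  knownP <- names(.CONFIG_DEFAULTS$params)
  extraP <- setdiff(names(p), knownP)
  if (length(extraP)) {
    stop(sprintf("unknown key(s) in 'params': %s", paste(extraP, collapse = ", ")),
      call. = FALSE)
  }
  for (key in c("k_f", "k_j", "k_r")) {
    if (!.isNumber(p[[key]]) || p[[key]] < 0) {
      stop(sprintf("'params.%s' must be a non-negative number", key), call. = FALSE)
    }
  }
  if (!.isNumber(p$V) || p$V <= 0) stop("'params.V' must be positive", call. = FALSE)
  if (!.isCount(p$n_E)) stop("'params.n_E' must be a positive integer", call. = FALSE)
  if (!.isCount(p$L_min)) stop("'params.L_min' must be a positive integer", call. = FALSE)
  if (!.isCount(p$L_c) || p$L_c <= p$L_min) {
    stop("'params.L_c' must be an integer greater than 'params.L_min'", call. = FALSE)
  }
  g <- out$generator
  if (!g$name %in% names(.GENERATOR_FIELDS)) {
    stop(sprintf("'generator.name' must be one of: %s",
      paste(names(.GENERATOR_FIELDS), collapse = ", ")), call. = FALSE)
  }
  e <- out$experiment
  if (!e$kind %in% .EXPERIMENT_KINDS) {
    stop(sprintf("'experiment.kind' must be one of: %s",
      paste(.EXPERIMENT_KINDS, collapse = ", ")), call. = FALSE)
  }
  if (!.isCount(e$n_samples)) stop("'experiment.n_samples' must be a positive integer", call. = FALSE)
  if (!.isNumber(e$master_seed)) stop("'experiment.master_seed' must be an integer", call. = FALSE)
  out
}

#' Read / write a run configuration
#'
#' The configuration format is YAML (the package's single canonical config
#' dialect) with sections `params`, `generator`, `experiment`, `output`;
#' omitted keys take the documented defaults and unknown keys are rejected
#' by name. `read(write(cfg))` round-trips losslessly.
#'
#' @param path YAML file path.
#' @param config a validated configuration list.
#' @return `readRunConfig` returns the validated, default-filled
#'   configuration list; `writeRunConfig` its `config`, invisibly.
#' @export
readRunConfig <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop(sprintf("cannot parse '%s': %s", path, conditionMessage(e)), call. = FALSE)
  })
  if (is.null(cfg)) cfg <- list()
  .validateConfig(cfg)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  config <- .validateConfig(config)
  yaml::write_yaml(config, path)
  invisible(config)
}

#' @rdname readRunConfig
#' @export
configParams <- function(config) {
  p <- .validateConfig(config)$params
  SimParams(
    kf = p$k_f, nE = p$n_E, kj = p$k_j, kr = p$k_r,
    Lmin = p$L_min, Lc = p$L_c, V = p$V,
    includeIrreparable = p$include_irreparable, tMax = p$t_max
  )
}

#' @rdname readRunConfig
#' @param seed RNG seed for stochastic generators.
#' @export
configDistribution <- function(config, seed = NULL) {
  config <- .validateConfig(config)
  g <- config$generator
  params <- configParams(config)
  dist <- switch(g$name,
    fixed_length = fixedLengthDistribution(g$M0, g$n, params),
    uniform_random = uniformRandomDistribution(g$k_species,
      as.integer(g$length_range), as.integer(g$count_range), seed, params),
    two_class = twoClassDistribution(g$M0, g$p_short,
      if (is.null(g$short_range)) NULL else as.integer(g$short_range),
      if (is.null(g$long_range)) NULL else as.integer(g$long_range),
      seed, params),
    preset = radiationPreset(g$preset, g$M0, seed, params),
    fraction_pair = fractionPairDistribution(g$M0, g$q1, g$q2, seed, params,
      if (is.null(g$long_max)) 3000L else as.integer(g$long_max)),
    file = readFragmentDistribution(g$path)
  )
  if (!is.null(g$p_irr) && g$p_irr > 0) {
    dist <- addIrreparable(dist, g$p_irr,
      if (is.null(g$irr_range)) NULL else as.integer(g$irr_range),
      seed = if (is.null(seed)) NULL else deriveSeed(seed, 31L), params = params)
  }
  dist
}

## ---- CLI -----------------------------------------------------------------

.cliMessage <- function(...) message("[nhejsim] ", sprintf(...))

.writeTSV <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE)
  invisible(path)
}

.cliCommonOptions <- function() {
  list(
    optparse::make_option("--config", type = "character", default = NULL,
      help = "YAML run configuration"),
    optparse::make_option("--dist", type = "character", default = NULL,
      help = "initial distribution TSV (length<TAB>count)"),
    optparse::make_option("--preset", type = "character", default = NULL,
      help = "radiation preset: fe_ion or gamma"),
    optparse::make_option("--m0", type = "integer", default = NULL,
      help = "total fragment count for generators"),
    optparse::make_option("--seed", type = "integer", default = NULL,
      help = "master seed"),
    optparse::make_option("--n-samples", type = "integer", default = NULL,
      dest = "n_samples", help = "replicates per ensemble"),
    optparse::make_option("--t-max", type = "double", default = NULL,
      dest = "t_max", help = "time horizon"),
    optparse::make_option("--out", type = "character", default = NULL,
      help = "output path prefix")
  )
}

.cliResolveConfig <- function(opt) {
  cfg <- if (!is.null(opt$config)) readRunConfig(opt$config) else .validateConfig(list())
  if (!is.null(opt$dist)) cfg$generator <- list(name = "file", path = opt$dist)
  if (!is.null(opt$preset)) {
    cfg$generator$name <- "preset"
    cfg$generator$preset <- opt$preset
    if (is.null(cfg$generator$M0)) cfg$generator$M0 <- 200L
  }
  if (!is.null(opt$m0)) cfg$generator$M0 <- opt$m0
  if (!is.null(opt$seed)) cfg$experiment$master_seed <- opt$seed
  if (!is.null(opt$n_samples)) cfg$experiment$n_samples <- opt$n_samples
  if (!is.null(opt$t_max)) cfg$params$t_max <- opt$t_max
  if (!is.null(opt$out)) cfg$output$prefix <- opt$out
  .validateConfig(cfg)
}

.cliEcho <- function(cfg, prefix) {
  path <- paste0(prefix, ".config.yaml")
  writeRunConfig(cfg, path)
  .cliMessage("effective configuration echoed to %s", path)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (one trajectory), `ensemble` (rejoining-time
#' statistics), `sweep` (parameter sweep), `surface` (short-fraction
#' surface), `kinetics` (mean fraction-remaining curve), `oracle` (exact
#' small-system mean rejoining time) and `gen-dist` (write a generated
#' distribution). Outputs are tab-separated tables plus a YAML echo of the
#' effective configuration; a master seed is mandatory for ensemble-style
#' commands, so there is no silent nondeterminism. Invoke from a shell via
#' the installed script: `Rscript <pkg>/scripts/nhejsim <subcommand> ...`.
#'
#' @param argv character vector of command-line arguments (subcommand
#'   first).
#' @return Exit code, invisibly: 0 success, 1 runtime failure, 2 usage
#'   error.
#' @export
runCLI <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: nhejsim <subcommand> [options]",
    "subcommands: simulate ensemble sweep surface kinetics oracle gen-dist",
    sep = "\n")
  if (!length(argv) || argv[1L] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(if (length(argv)) 0L else 2L))
  }
  sub <- argv[1L]
  rest <- argv[-1L]
  handlers <- list(
    simulate = .cliSimulate, ensemble = .cliEnsemble, sweep = .cliSweep,
    surface = .cliSurface, kinetics = .cliKinetics, oracle = .cliOracle,
    `gen-dist` = .cliGenDist
  )
  if (!sub %in% names(handlers)) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(2L))
  }
  code <- tryCatch(
    handlers[[sub]](rest),
    usageError = function(e) {
      message("usage error: ", conditionMessage(e))
      2L
    },
    error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    }
  )
  invisible(code)
}

.usageStop <- function(msg) {
  stop(structure(class = c("usageError", "error", "condition"),
    list(message = msg, call = NULL)))
}

.cliParse <- function(args, extra = list()) {
  parser <- optparse::OptionParser(option_list = c(.cliCommonOptions(), extra))
  tryCatch(
    optparse::parse_args(parser, args = args),
    error = function(e) .usageStop(conditionMessage(e)),
    warning = function(e) .usageStop(conditionMessage(e))
  )
}

.cliNeedSeed <- function(cfg, opt) {
  if (is.null(opt$seed) && is.null(opt$config)) {
    .usageStop("a master seed is required (--seed or a config file)")
  }
  as.integer(cfg$experiment$master_seed)
}

.cliSimulate <- function(args) {
  opt <- .cliParse(args)
  cfg <- .cliResolveConfig(opt)
  seed <- .cliNeedSeed(cfg, opt)
  params <- configParams(cfg)
  dist <- configDistribution(cfg, seed = deriveSeed(seed, 17L))
  tr <- simulateRejoining(dist, params, seed = seed)
  prefix <- cfg$output$prefix
  .writeTSV(as.data.frame(tr), paste0(prefix, ".trajectory.tsv"))
  .cliMessage("trajectory: %d events, status '%s'%s",
    length(tr@times), tr@status,
    if (tr@status == "completed") sprintf(", rejoining time %g", rejoiningTime(tr)) else "")
  .cliEcho(cfg, prefix)
  0L
}

.cliEnsemble <- function(args) {
  opt <- .cliParse(args)
  cfg <- .cliResolveConfig(opt)
  cfg$experiment$kind <- "ensemble"
  seed <- .cliNeedSeed(cfg, opt)
  params <- configParams(cfg)
  dist <- configDistribution(cfg, seed = deriveSeed(seed, 17L))
  summ <- replicateTimes(dist, params, cfg$experiment$n_samples, seed)
  prefix <- cfg$output$prefix
  .writeTSV(as.data.frame(summ), paste0(prefix, ".ensemble.tsv"))
  .cliMessage("ensemble: n = %d, mean rejoining time %g", summ@nSamples, meanTime(summ))
  .cliEcho(cfg, prefix)
  0L
}

.cliSweep <- function(args) {
  opt <- .cliParse(args, list(
    optparse::make_option("--parameter", type = "character", default = NULL),
    optparse::make_option("--values", type = "character", default = NULL,
      help = "comma-separated sweep values")
  ))
  if (is.null(opt$parameter) || is.null(opt$values)) {
    .usageStop("sweep requires --parameter and --values")
  }
  cfg <- .cliResolveConfig(opt)
  cfg$experiment$kind <- "sweep"
  cfg$experiment$parameter <- opt$parameter
  cfg$experiment$values <- as.numeric(strsplit(opt$values, ",", fixed = TRUE)[[1L]])
  seed <- .cliNeedSeed(cfg, opt)
  params <- configParams(cfg)
  g <- cfg$generator
  tab <- parameterSweep(params, opt$parameter, cfg$experiment$values,
    nSamples = cfg$experiment$n_samples, masterSeed = seed,
    dist = if (opt$parameter %in% c("V", "k_r")) configDistribution(cfg, deriveSeed(seed, 17L)) else NULL,
    M0 = if (is.null(g$M0)) 20L else g$M0,
    length = if (is.null(g$n)) 100L else g$n)
  prefix <- cfg$output$prefix
  .writeTSV(tab, paste0(prefix, ".sweep.tsv"))
  .cliMessage("sweep over %s: %d points written", opt$parameter, nrow(tab))
  .cliEcho(cfg, prefix)
  0L
}

.cliSurface <- function(args) {
  opt <- .cliParse(args, list(
    optparse::make_option("--q1", type = "character", default = "0,0.2,0.4"),
    optparse::make_option("--q2", type = "character", default = "0,0.2,0.4"),
    optparse::make_option("--n-distributions", type = "integer", default = 10L,
      dest = "n_distributions")
  ))
  cfg <- .cliResolveConfig(opt)
  cfg$experiment$kind <- "surface"
  seed <- .cliNeedSeed(cfg, opt)
  params <- configParams(cfg)
  q1 <- as.numeric(strsplit(opt$q1, ",", fixed = TRUE)[[1L]])
  q2 <- as.numeric(strsplit(opt$q2, ",", fixed = TRUE)[[1L]])
  cfg$experiment$q1_grid <- q1
  cfg$experiment$q2_grid <- q2
  cfg$experiment$n_distributions <- opt$n_distributions
  M0 <- if (is.null(cfg$generator$M0)) 20L else cfg$generator$M0
  tab <- fractionSurface(params, q1, q2, M0 = M0,
    nDistributions = opt$n_distributions,
    nSamples = cfg$experiment$n_samples, masterSeed = seed)
  prefix <- cfg$output$prefix
  .writeTSV(tab, paste0(prefix, ".surface.tsv"))
  .cliMessage("surface: %d grid points written", nrow(tab))
  .cliEcho(cfg, prefix)
  0L
}

.cliKinetics <- function(args) {
  opt <- .cliParse(args, list(
    optparse::make_option("--grid-points", type = "integer", default = 101L,
      dest = "grid_points")
  ))
  cfg <- .cliResolveConfig(opt)
  cfg$experiment$kind <- "kinetics"
  seed <- .cliNeedSeed(cfg, opt)
  params <- configParams(cfg)
  horizon <- if (is.finite(params@tMax)) params@tMax else 50
  grid <- seq(0, horizon, length.out = opt$grid_points)
  dist <- configDistribution(cfg, seed = deriveSeed(seed, 17L))
  curve <- meanKinetics(dist, params, cfg$experiment$n_samples, grid, seed)
  prefix <- cfg$output$prefix
  .writeTSV(as.data.frame(curve), paste0(prefix, ".kinetics.tsv"))
  .cliMessage("kinetics: P(%g) = %.4f", horizon, curve@P[length(curve@P)])
  .cliEcho(cfg, prefix)
  0L
}

.cliOracle <- function(args) {
  opt <- .cliParse(args, list(
    optparse::make_option("--fixture", type = "character", default = NULL,
      help = "closed-form fixture: two-short"),
    optparse::make_option("--a", type = "double", default = 1),
    optparse::make_option("--b", type = "double", default = 1)
  ))
  if (!is.null(opt$fixture)) {
    if (opt$fixture != "two-short") .usageStop("unknown oracle fixture: " %+% opt$fixture)
    value <- closedFormTwoShort(a = opt$a, b = opt$b)
  } else {
    cfg <- .cliResolveConfig(opt)
    params <- configParams(cfg)
    dist <- configDistribution(cfg,
      seed = if (is.null(opt$seed)) NULL else deriveSeed(opt$seed, 17L))
    value <- exactMeanRejoiningTime(dist, params)
  }
  cat(format(value, digits = 12), "\n", sep = "")
  0L
}

`%+%` <- function(a, b) paste0(a, b)

.cliGenDist <- function(args) {
  opt <- .cliParse(args)
  cfg <- .cliResolveConfig(opt)
  seed <- .cliNeedSeed(cfg, opt)
  dist <- configDistribution(cfg, seed = seed)
  out <- if (!is.null(opt$out)) opt$out else paste0(cfg$output$prefix, ".dist.tsv")
  writeFragmentDistribution(dist, out)
  .cliMessage("distribution: %d fragments over %d lengths written to %s",
    totalFragments(dist), length(dist@lengths), out)
  0L
}
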