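Package: NHEJsim
Title: Stochastic Simulation of DNA Fragment Rejoining by Ku-Dependent
    Non-Homologous End Joining
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Exact stochastic simulation (Gillespie's direct method) of a
    reaction-network model of DNA double-strand-break repair by Ku-dependent
    non-homologous end joining. Radiation-induced DNA fragments recruit a
    generic repair protein (Ku) at their free ends, join pairwise at
    protein-bound ends, and, when a joining partner is shorter than the
    critical length for simultaneous double Ku occupancy, leave a protein
    residue at the junction that must be released before new recruitment.
    The package provides the deterministic state-update semantics of the
    three reaction classes, a reproducible direct-method engine producing
    event trajectories and rejoining times, generators for initial
    fragment-length distributions (fixed-length, uniform-random,
    radiation-quality two-class presets, fraction-pair sampling, and
    irreparable sub-minimum fragments), ensemble experiments (rejoining-time
    statistics, parameter sweeps over nuclear volume, release rate, fragment
    number and length, short-fraction surfaces, and mean fraction-remaining
    kinetics), an exact continuous-time Markov-chain solver used to validate
    the stochastic engine on small systems, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'params.R'
    'state.R'
    'distributions.R'
    'gillespie.R'
    'ctmc.R'
    'ensemble.R'
    'io.R'
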