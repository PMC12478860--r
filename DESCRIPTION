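Package: cgdroplet
Title: Coarse-Grained Simulation and Analysis of Protein-DNA Condensates
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A minimalist coarse-grained model of protein-DNA biomolecular
    condensates: single-bead proteins and bead-spring DNA interacting through
    an Ashbaugh-Hatch pair potential, integrated with Langevin dynamics in a
    periodic cubic box. Includes a Monte Carlo pivot sampler for isolated
    chains and a full analysis stack: distance-based clustering with
    largest-cluster composition, chain compaction and persistence length,
    multiphasic radial density profiles with double hyperbolic tangent fits
    and coexistence concentrations, and decomposition of radial displacement
    distributions into multiple diffusive modes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
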