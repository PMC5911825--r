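Package: covfes
Title: Free-Energy Surfaces for Covalent-Inhibition Simulation Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the free-energy side of covalent kinase-inhibitor
    modelling: umbrella-sampling window ladders and grids, a weighted
    histogram analysis method (WHAM) solver producing unbiased 1D/2D
    free-energy surfaces with overlap, normality and convergence
    diagnostics, minimax (lowest-saddle) reaction-path extraction with
    activation and reaction free energies, Boltzmann-inversion
    conformational surfaces from unbiased trajectory feature tables,
    reactive-conformation statistics, thermodynamic-integration
    quadrature, and calibrated synthetic generators (analytic two-well
    reaction surfaces sampled by Metropolis Monte Carlo, two-state Markov
    trajectories, toy PDB fixtures) with quadrature-verified ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
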