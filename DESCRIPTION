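Package: mdem
Title: Data-Driven Rigid-Body Pair Potentials and Anisotropic Langevin
    Self-Assembly Simulation
Version: 0.1.0
Authors@R: person("MDEM", "Maintainers", email = "mdem@example.org",
    role = c("aut", "cre"))
Description: Tools for the molecular discrete element abstraction of
    macromolecular self-assembly. Learns six-dimensional rigid-body
    pair-interaction potentials from a sampling oracle by Universal
    Kriging (minimum-distance trend models, sectional residual
    variograms, SVD-regularised kriging systems, supervised iterative
    refinement), converts them to potential grids yielding forces and
    torques by central differences, and drives anisotropic Langevin
    dynamics of rigid bodies under periodic boundary conditions.
    Includes synthetic benchmark generators (sequential Gaussian
    simulation, patchy-particle oracles, a capsid pose fixture),
    Rotne-Prager-Yamakawa drag utilities, and assembly analytics
    (contact classification, cluster statistics, size-class
    transitions, lifetimes, kinetics fits).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
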