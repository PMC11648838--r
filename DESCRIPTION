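Package: prime20samc
Title: Flat-Histogram Sampling, Backmapping and Energy Calibration for a
    Coarse-Grained Peptide Model
Version: 0.1.0
Authors@R: person("prime20samc", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stochastic-approximation Monte Carlo (SAMC) estimation of the
    density of states of a four-bead coarse-grained peptide model with
    square-well hydrogen-bond and sidechain interactions, fixed-DOS
    production sampling with stratified snapshot collection, inverse
    coarse-graining (backmapping) of coarse-grained snapshots to all-atom
    structures with steric-clash reporting, and the calibration statistics
    (effective-sample standard errors, running averages, half-split checks,
    ordinary-least-squares energy calibration) used to assign a physical
    energy scale to the dimensionless model energies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
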