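Package: fretdyn
Title: Hybrid Single-Molecule and Ensemble FRET Analysis of Exchanging
    Conformational States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for resolving conformational states of biomolecules that
    exchange on microsecond-to-millisecond timescales from fluorescence
    spectroscopy, developed around the three-state hinge-bending dynamics of
    T4 lysozyme. Provides a Brownian-dynamics photon-stream simulator for
    confocal single-molecule FRET experiments, burst selection and
    multiparameter fluorescence detection (MFD) indicators with static and
    dynamic FRET-lines, species-filtered fluorescence correlation
    spectroscopy (fFCS), global fitting of ensemble TCSPC decays with
    Gaussian donor-acceptor distance distributions (support-plane and MCMC
    uncertainties), inversion of three-state kinetic networks from
    relaxation times and species fractions, accessible-contact-volume dye
    models with FRET screening of structural models, and a
    kappa-squared-based distance uncertainty budget.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
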