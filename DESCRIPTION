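Package: clutchms
Title: Multi-Scale Motor-Clutch Simulation of Cell Adhesion Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of integrin-based adhesion complexes at the
    scale of individual adhesion molecules. Couples an actomyosin force-velocity
    relation, a 13-domain talin rod with freely-jointed-chain / worm-like-chain
    mechanics and per-domain folding kinetics, integrin catch/slip bond kinetics
    with vinculin-triggered density reinforcement, and an elastic half-space
    substrate resolved per ligand through Green's functions. A Gillespie engine
    with a nonlinear per-event force balance drives the multi-scale model; the
    classical single-spring Monte-Carlo clutch model is included as a baseline.
    Experiment drivers reproduce substrate-stiffness sweeps, single-chain pulling,
    parameter sensitivity scans and ligand-spacing studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
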