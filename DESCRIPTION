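Package: stempbe
Title: Stochastic Population Balance Modeling of Stem Cell Size and NANOG Heterogeneity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multiscale stochastic population balance equation (PBE) framework
    for self-renewing human embryonic stem cell populations. Couples
    exponential single-cell size growth, a size-gated division hazard with
    symmetric beta partitioning of cellular content, and an Euler-Maruyama
    stochastic differential equation for NANOG copy number. Provides a
    constant-volume/constant-number Monte Carlo solver based on
    interval-of-quiescence sampling, an independent finite-difference solver
    for the size-structured PBE, intrinsic/extrinsic noise decomposition via
    virtual dual-reporter assays, simulation-based parameter estimation from
    flow-cytometry-style distributions, MESF bead calibration utilities, and a
    synthetic flow-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, CellBiology, SingleCell, FlowCytometry, StemCell,
    MathematicalBiology
RoxygenNote: 7.3.3
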