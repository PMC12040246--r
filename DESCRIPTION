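Package: voHypertrophyNet
Title: Bayesian Calibration of Logic-Based Hypertrophy Signaling Networks
    Under Ventricular Volume Overload
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for probabilistic meta-analysis of eccentric cardiac
    hypertrophy during ventricular volume overload. Implements a logic-based
    signaling network simulator with normalized Hill activation kinetics,
    a thin-walled-sphere model of end-diastolic myofiber stretch and
    Lagrangian strain with growth feedback, cross-species time normalization
    and fitting of time-varying hormonal fold-change curves, two-stage
    Metropolis-Hastings/Gibbs calibration of input reaction weights against
    mean and standard deviation literature observations, and Monte Carlo
    scenario ensembles (volume overload, agonist infusion, receptor
    blockade) with confidence-interval, classification, and Pearson
    correlation sensitivity summaries. Includes a synthetic-data generator
    producing toy networks and literature-like observation tables from known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    deSolve,
    minpack.lm,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
biocViews: SystemsBiology, NetworkInference, Bayesian, GraphAndNetwork
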