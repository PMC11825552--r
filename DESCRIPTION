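Package: txapk
Title: Population Pharmacokinetics of Tranexamic Acid During Cardiac
    Surgery with Cardiopulmonary Bypass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear mixed-effects analysis of tranexamic acid
    concentration-time data from cardiac surgery with cardiopulmonary
    bypass (CPB). Implements closed-form one- and two-compartment
    intravenous bolus models with dose superposition, power-law covariate
    submodels (body weight, Cockcroft-Gault creatinine clearance),
    log-normal inter-individual variability and a combined residual error
    model, estimated by a first-order conditional (FOCE) approximation
    with interaction. Includes likelihood-ratio model comparison, an
    exhaustive ("shotgun") covariate search, goodness-of-fit diagnostics
    (PRED, IPRED, CWRES), visual predictive checks, nonparametric
    bootstrap, NONMEM-style event-record input/output, and a synthetic
    cohort generator emulating a double-bolus CPB study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    optparse
Config/testthat/edition: 3
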