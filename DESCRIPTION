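Package: bvselect
Title: Model Selection Tools for Blood-Volume Response to Hemorrhage and
    Fluid Resuscitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, calibration and comparison of lumped-parameter
    models of the blood-volume (BV) response to fluid infusion and
    hemorrhage, intended for evaluating physiological closed-loop
    controlled (PCLC) fluid-resuscitation devices.  Implements two
    candidate models (a static-reference original model and a refined
    model with first-order reference dynamics), exact zero-order-hold
    simulation, penalized maximum-likelihood calibration with inner
    penalty selection, structural-identifiability coefficient maps,
    variance-based first-order (Sobol) sensitivity analysis, a
    multi-dimensional calibration measure, and three predictive-capability
    scenarios scored with prediction envelopes, interval scores and
    coverage proportions.  A synthetic-cohort generator emulates a sheep
    hemorrhage/resuscitation protocol so the whole pathway runs
    end-to-end without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
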