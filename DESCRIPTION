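Package: counterreg
Title: Population Modelling of Counter-Regulatory Hormone Secretion During Glucose Clamps
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Turnover and pool (indirect-response) models of glucagon, ACTH
    and cortisol secretion driven by plasma glucose and insulin during
    hyperinsulinemic hypo- and hyperglycemic clamps. Provides the structural
    effect functions (sigmoidal Imax/Emax with Hill factors, effect-compartment
    delay), log-normal between-subject and between-occasion variability,
    exponential covariate models of insulin sensitivity (GIR) on potencies,
    simulation of clamp study designs, fully synthetic longitudinal datasets
    with proportional residual error and below-quantification flagging,
    maximum-likelihood estimation with BLQ-inflated residual error, model
    comparison by likelihood-ratio test and AIC, bootstrap standard errors,
    stepwise covariate modelling, visual predictive checks, and closed-form
    suppression thresholds (glucose for ACTH inhibition, insulin for glucagon
    inhibition).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
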