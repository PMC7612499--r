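Package: myofit
Title: Two-Step Multi-Fidelity Personalisation of Cardiac Active Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates cardiac active-mechanics models to left-ventricular
    pressure and volume data with a two-step multi-fidelity workflow. Step one
    personalises a phenomenological hyperbolic-tangent active-stress model and
    diode valve resistances at the organ scale by fixed-point iteration on
    pressure and volume biomarkers, using a lumped (0D) ventricle coupled to a
    three-element Windkessel afterload. Step two personalises a biophysically
    detailed crossbridge model (Land-type active stress with a phenomenological
    calcium transient and a three-element passive element) at the cell scale by
    constrained differential evolution on a 0D electromechanics model that
    solves the active/passive stress equilibrium for the fibre-stretch
    trajectory. Includes variance-based Sobol sensitivity analysis with
    Saltelli sampling, robustness protocols for clinical-data uncertainty and
    initial-guess variation, biomarker extractors for pressure, volume, stress,
    calcium and stretch traces, and synthetic data generators for testing the
    full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
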