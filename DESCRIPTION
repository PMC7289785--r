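Package: pulsepkpd
Title: Population PK/PD Modelling of Pulsatile Growth Hormone and Circadian
    Prolactin Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deconvolution-informed population pharmacokinetic/
    pharmacodynamic analysis of endogenous pituitary hormones under a
    somatostatin-dopamine receptor agonist. Growth hormone is modelled as
    Gaussian secretion pulses on a basal secretion rate with first-order
    elimination and an effect-compartment Emax inhibition of pulse mass;
    prolactin as a precursor pool with two-harmonic circadian release,
    direct plasma-driven Emax inhibition of release, and a cumulative
    exposure driven decline in synthesis. Includes an insert-test-remove
    pulse deconvolution, a FOCE-style nonlinear mixed-effects estimator
    with inter-individual and between-occasion variability, model
    diagnostics (CWRESI, NPDE, prediction-corrected VPC, shrinkage,
    covariate screening), and a virtual phase-1 ascending-dose trial
    simulator with assay noise and LLOQ censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
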