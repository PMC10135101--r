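Package: penpk
Title: Population Pharmacokinetics and Dosing Simulation of
    Benzylpenicillin in Critical Illness
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of intravenous
    benzylpenicillin in critically ill adults: analytic one- and
    two-compartment disposition under arbitrary bolus and infusion
    schedules, nonlinear mixed-effects estimation by first-order
    conditional estimation with interaction (FOCE-i), allometric weight
    scaling and power-law covariate models on clearance, stepwise
    covariate selection by likelihood-ratio testing, non-parametric
    bootstrap, goodness-of-fit and prediction-corrected visual predictive
    checks, and Monte-Carlo dosing simulations that report the
    probability of attaining free-drug time-above-MIC (%fT>MIC) targets
    for bolus, extended-infusion and continuous-infusion regimens.
    Includes a synthetic study generator emulating an opportunistically
    sampled critical-care study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
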