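Package: gadlife
Title: Coupled Age-Structured Life-Cycle State-Space Models for Cod and
    Haddock
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Age-structured life-cycle state-space models for two
    interacting harvested gadoids, Northeast Arctic haddock and Atlantic
    cod. Provides forward simulators for the process and observation
    models (temperature-dependent recruitment, cod-predation and
    density-dependent juvenile mortality, effort random-walk fishing
    mortality, Baranov catches, lognormal survey and landings
    observations), Bayesian estimation of parameters and latent
    abundances by adaptive Markov chain Monte Carlo with convergence
    diagnostics, a hindcasting engine that propagates cod
    harvest-intensity scenarios into haddock population trajectories,
    error-weighted smooth regressions of stage-specific abundance on
    temperature and on cod inter-cohort interaction strength, and a
    synthetic-data generator emulating ICES-style age-by-year tables for
    simulation testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    mgcv,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
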