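Package: npbclock
Title: Non-Invasive Physiology and Behavior Age Clocks for Longitudinal
    Animal Cohorts
Version: 0.1.0
Authors@R:
    person("NPB", "Clock Developers", email = "npbclock@example.org",
           role = c("aut", "cre"))
Description: Builds biological-age clocks from annual panels of
    non-invasively measured physiological and behavioral traits in
    longitudinal animal studies. Provides trait screening for linear and
    quadratic age associations via AIC-selected mixed models, two-phase
    imputation (adjacent-year filling followed by chained predictive mean
    matching with leakage-safe train/test splits), a random-forest
    regression clock with prediction averaging across imputations,
    relative-age and repeatability summaries, time-varying Cox
    proportional-hazards models linking relative age to mortality, and
    cumulative early-life adversity indices. Includes a synthetic-cohort
    generator with known latent frailty so every pipeline stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    survival,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
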