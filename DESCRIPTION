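Package: dietshock
Title: Diet Diversity and Quality Scoring and Price-Shock Association Models for Household Food-Security Surveys
Version: 0.1.0
Authors@R: person("ARISE", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing 7-day food-group recall data from multi-site
    household food-security surveys. Scores recalls into an adapted Minimum
    Dietary Diversity for Women count (DDS, 0-10) and an adapted Prime Diet
    Quality Score (PDQS, 0-40), codes food-price-shock and food-insecurity
    exposures, reproduces stratified descriptive tables and before/during
    consumption-change summaries, and estimates exposure-diet associations
    with exchangeable-correlation generalized estimating equations clustered
    by site, including univariate covariate screening with forced terms and
    missing-indicator confounder adjustment. Ships a configurable six-site
    synthetic-survey generator with a Monte-Carlo oracle for implied
    score-level effects, and a command-line pipeline for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
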