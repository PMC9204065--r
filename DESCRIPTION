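Package: rtiburst
Title: Dissociating Retest Effects from Developmental Change in Response-Time
    Inconsistency with Measurement-Burst Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing response-time inconsistency (RTI) in
    longitudinal measurement-burst studies of cognitive aging. Implements
    trial-level quality control (latency bounds, accuracy and missingness
    screening), residualized intraindividual standard deviation (ISD) scores
    with T standardization, a three-level linear mixed model fit by full
    maximum likelihood that separates short-term (weekly, retest) from
    long-term (yearly, developmental) change, empirical-Bayes extraction of
    person-specific slopes, normative cognitive-status classification
    (HC/CIND-S/CIND-M), and multinomial logistic regression linking the
    extracted slopes to prospective cognitive status. A fully seeded
    synthetic-data generator reproduces the statistical structure of a
    biweekly measurement-burst study for simulation and parameter-recovery
    work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    nnet,
    withr
Config/testthat/edition: 3
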