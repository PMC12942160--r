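Package: agestage
Title: Age-Stage, Two-Sex Life Table Analysis for Insect Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the age-stage, two-sex life table analysis of daily
    insect rearing records. Computes age-stage survival, fecundity, life
    expectancy and reproductive value schedules, the stable age-stage
    distribution, and the scalar demographic parameters (net reproductive
    rate, intrinsic rate of increase, finite rate, mean generation time)
    from per-individual daily censuses. Provides individual-resampling
    bootstrap standard errors and confidence intervals, a paired-bootstrap
    treatment comparison, a deterministic stage-structured population
    projection, summary tables for stage durations, reproduction and
    mortality distribution, and a stochastic cohort generator with exact
    theoretical schedules for validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
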