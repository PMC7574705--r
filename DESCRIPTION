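Package: musclebone
Title: Cross-Lagged Panel Models of Reciprocal Muscle-Bone Relationships
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of DXA body-composition cohorts:
    a three-wave cross-lagged panel model of lean mass and areal bone mineral
    density with equality-constrained autoregressive paths, fitted by normal-theory
    maximum likelihood on the sample covariance matrix; absolute, parsimonious and
    relative fit indices (chi-square, SRMR, RMSEA with noncentral confidence
    interval, Bentler-Bonett NFI) with a two-of-four adequacy rule; path-analytic
    decomposition of cross-lagged effects into direct and indirect components over
    parallel mediation routes with delta-method standard errors; visit-level
    descriptive summaries with repeated-measures contrasts, per-participant percent
    change, annualization and LMS reference z-scores; post hoc general linear
    models for baseline predictors of subsequent change; and a calibrated
    three-wave synthetic cohort generator so every stage is testable without
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
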