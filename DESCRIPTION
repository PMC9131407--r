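Package: vptbias
Title: Analysis and Simulation of Spontaneous Visual Perspective-Taking
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for mental-rotation experiments that probe spontaneous
    visual perspective taking. Implements the vector-projection summary
    statistics (towards/away and left/right biases) over per-orientation
    response-time profiles, per-participant dual-viewpoint rotation
    regressions with orthogonal self- and other-disparity predictors,
    within-subject inference (repeated-measures ANOVA with
    Greenhouse-Geisser correction, JZS and Jeffreys Bayes factors by
    numerical quadrature, power analysis via the noncentral t
    distribution), questionnaire scoring (AQ, IRI, STQ-STA) with
    correlation and hierarchical-regression analyses of individual
    differences, and a synthetic-cohort generator with an ex-Gaussian
    response-time model and a Gaussian questionnaire copula so that every
    stage of the pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
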