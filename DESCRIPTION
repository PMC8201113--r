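Package: kanoqual
Title: Kano Model Analysis of Service Quality Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing paired functional/dysfunctional quality
    questionnaires with the Kano model. Classifies each answer pair into one
    of six quality categories (attractive, one-dimensional, must-be,
    indifferent, reverse, questionable) via a configurable 5 x 5 evaluation
    matrix, aggregates per-attribute category counts, assigns the modal
    attribute classification, and computes the Berger satisfaction (CS) and
    dissatisfaction (DS) coefficients. Includes standardized Cronbach's alpha
    for item reliability, a seeded synthetic-respondent simulator, a
    deterministic count-to-respondent expander, CS-|DS| quadrant charts, and
    a small command-line interface. Ships the 31-attribute HEALTHQUAL-derived
    hospital instrument and the published per-attribute category counts from
    a 250-user two-hospital survey as worked reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    optparse,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
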