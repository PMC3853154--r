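Package: ciboost
Title: Gradient-Boosted Concordance-Index Learning for Censored Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains ensembles of shallow regression trees for right-censored
    survival data by directly maximizing a sigmoid-smoothed concordance index
    via gradient boosting, alongside a boosted Cox partial-likelihood model
    and a linear Cox proportional-hazards baseline fitted by Newton-Raphson.
    Includes exact comparable-pair enumeration, Harrell-style concordance
    evaluation with configurable tie handling, seeded simulators for
    proportional-hazards and nonlinear-risk cohorts with calibrated censoring,
    cross-validated selection of the ensemble size, JSON model serialization,
    and a command-line interface for simulate/train/predict/evaluate
    workflows.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
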