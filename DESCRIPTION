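Package: carceff
Title: Distinguishing Positive Selection from Cancer Causation in Somatic Mutation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators of per-mutation carcinogenic effect from paired
    cancer/normal-tissue mutation frequencies (matched odds ratio with donor
    bootstrap, gene-length benchmark, hybrid Beta regression, logistic
    regression with age and burden covariates); a birth-death branching-process
    model of lifelong somatic evolution with carcinogenesis, solved by backward
    Kolmogorov equations and cross-checked by exact stochastic simulation;
    age-distribution statistics for cancer cohorts including a permutation test
    of the null hypothesis of non-carcinogenicity and rank-biserial age-bias
    comparisons of copy-number versus point alterations; a multi-hit
    carcinogenesis simulator; and synthetic-cohort generators so that every
    component is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
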