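Package: guessnull
Title: Monte Carlo Guessing Baselines for Source Errors in Paired Action Recall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired generation/recall experiments on
    source memory for actions. Classifies recalled items as correct recalls,
    source errors or intrusion errors; estimates a per-participant Monte
    Carlo guessing baseline for source errors by weighted sampling without
    replacement from generation-phase frequency norms; compares observed
    with predicted source errors via one-tailed paired tests with d_av
    effect sizes, mixed ANOVA and within-subject confidence intervals;
    pools experiments with fixed-effect standardized-mean-change
    meta-analysis and half-normal-prior Bayes factors; and ships a
    generative simulator of the paired design for calibration and
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
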