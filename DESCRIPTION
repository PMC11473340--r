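Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for two-sample Mendelian randomization
    (MR) over GWAS summary statistics, built around a two-step mediation
    design (exposure -> mediator -> outcome). Provides reading, validation
    and harmonization of per-SNP association tables; instrument selection by
    p-value threshold, greedy LD clumping and confounder exclusion with
    F-statistic strength diagnostics; the inverse-variance weighted, MR-Egger
    and weighted-median causal estimators with Cochran's Q heterogeneity
    statistics; a simulation-based residual-sum-of-squares pleiotropy test
    with per-SNP outlier flagging and outlier-corrected re-estimation; the
    product-of-coefficients mediation calculus (indirect effect, delta-method
    standard error, proportion mediated); and an individual-level simulator
    of three non-overlapping GWAS cohorts with known causal structure for
    calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
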