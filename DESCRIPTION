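Package: vitdmr
Title: Two-Sample Mendelian Randomisation of Circulating Vitamin D and Cancer Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample summary-data Mendelian randomisation of
    circulating 25-hydroxyvitamin D (25(OH)D) concentration and cancer risk.
    Reads and harmonizes GWAS summary-statistic tables onto a common
    effect-allele orientation, estimates the causal log odds ratio per unit
    exposure with inverse-variance weighted, profile-likelihood, MR-Egger and
    weighted-median estimators, runs heterogeneity and pleiotropy diagnostics
    (Cochran's Q, over-identification, Egger intercept), rescales estimates to
    per-25 nmol/L odds ratios, computes statistical power and minimum
    detectable odds ratios for binary-outcome case-control designs, and
    simulates two-sample summary statistics with configurable causal effects
    and horizontal pleiotropy for method validation.
License: MIT
Encoding: UTF-8
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
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
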