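Package: epivasc
Title: Epigenetic and Vascular Age Analysis for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing epigenetic age, chronological age and
    vascular age in two-group clinical cohorts. Implements a five-CpG
    blood DNA-methylation age clock (ELOVL2, C1orf132/MIR29B2C, TRIM59,
    KLF14, FHL2) and age acceleration; the 2008 Framingham general
    cardiovascular disease risk function with vascular ("heart") age
    obtained by monotone inversion against a normal-risk-factor reference;
    HOMA-IR and glucose unit conversions; a rank-based group-comparison
    layer (Mann-Whitney rank-sum, chi-squared, Spearman correlations,
    median [IQR] summary tables); and a seeded synthetic cohort generator
    for pipeline testing and parameter-recovery studies.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
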