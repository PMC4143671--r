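Package: wfdrtrio
Title: Weighted False Discovery Rate Control for Trio-Based Association
    Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multiple-testing control for family-based genetic association
    studies of quantitative traits. Implements the weighted
    Benjamini-Hochberg false discovery rate procedure in which per-SNP
    p-values from a trio-based transmission test are reweighted by
    independent evidence from a population-based association scan, together
    with the surrounding pipeline: PLINK text ped/map input, genotype
    quality control, trio extraction from pedigrees, mean arterial pressure
    phenotype derivation, covariate-adjusted per-SNP regression, a
    stratification-robust within-family quantitative trio test, and a
    Mendelian trio simulator with a replication-counting power study
    comparing ordinary and weighted FDR control.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
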