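Package: pleiocca
Title: Gene-Based Pleiotropy Discovery with Canonical Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate association testing between gene-centred SNP blocks
    and sets of phenotypes using canonical correlation analysis (CCA) with
    Wilks' Lambda and Rao's F approximation, log-scale p-values, genetic
    algorithm subset search (single- and two-population cooperative
    coevolution), two-stage linkage-disequilibrium pruning (pairwise r-squared
    then variance inflation factor), k-nearest-neighbour phenotype imputation,
    genotype quality control, Fisher's combined probability, and Bonferroni
    correction over combinatorial rule search spaces. Includes a synthetic
    genotype/phenotype generator with controlled within-gene LD, phenotype
    correlation, planted pleiotropic effects and missingness, plus readers and
    writers for VCF, BED and TSV.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
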