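Package: pgtkaryo
Title: Karyotype and Crossover Inference from Preimplantation Genetic
    Testing SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers whole-chromosome and segmental aneuploidies of embryo
    biopsies from SNP-array B-allele frequencies given phased parental
    haplotypes, using a haplotype-copying hidden Markov model with a
    truncated-normal/point-mass emission model. Classifies trisomies by
    parental-homolog content (both parental homologs versus a single
    duplicated homolog) to separate putative meiotic from mitotic errors,
    calls meiotic crossovers in a template embryo against sibling embryos
    via a transmitted-allele likelihood ratio, and quantifies nucleus-wide
    covariation of crossover counts (law-of-total-variance decomposition,
    intraclass correlation, permutation null). Ships a synthetic-data
    generator that reproduces the validation design: haplotypes under
    Hardy-Weinberg equilibrium, phasing switch errors, array noise, mosaic
    multi-cell biopsies, and segmental events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
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
    withr
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
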