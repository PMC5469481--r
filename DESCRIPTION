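Package: kinmatch
Title: Genotype Fingerprinting, Duplicate Detection and Relationship
    Classification from Mismatch Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finds duplicate samples and close relatives in large SNP
    genotype collections, even across genotyping platforms. Extracts a
    panel of fingerprint SNPs from PLINK binary datasets, bit-packs
    genotypes two bits per SNP into 64-bit words, and compares sample
    pairs with popcount kernels to obtain the all-genotype mismatch rate
    (AGMR) and the homozygous genotype mismatch rate (HGMR). Provides
    naive, quadratic (early-termination) and sub-quadratic (sort-based)
    duplicate scanners with closed-form error-rate predictions, a Bayes
    classifier that assigns pairwise relationships (identical,
    parent-offspring, full sibling, second and third degree, unrelated)
    directly from the joint (HGMR, AGMR) statistics, pedigree concordance
    QC reports, and a gene-dropping simulator with known truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
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
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
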