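Package: beemethyl
Title: Genotype-Aware Caste- and Sex-Specific DNA Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-alignment analysis of whole-genome bisulfite sequencing
    (WGBS) for haplodiploid insects. Builds N-masked and individualised
    reference genomes from filtered parental SNPs, calls per-CpG methylation
    status against a lambda-spike non-conversion null with false-discovery
    control, tests caste and sex differential methylation by per-CpG binomial
    logistic regression with a subspecies covariate, relates methylation to
    codon fold degeneracy (beta regression, hypergeometric enrichment) and to
    selection signatures via pN/pS polymorphism ratios, and performs GO-term
    enrichment. Ships a synthetic-study generator with known truth so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
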