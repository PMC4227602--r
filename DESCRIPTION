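Package: rarescreen
Title: Rare-Variant Screening, Association and Linkage Disequilibrium for
    Candidate Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A whole-genome-sequencing candidate-gene workflow for
    rare-variant prioritisation and case-control analysis. Classifies
    variants into regulatory and coding region categories (promoter,
    untranslated regions, splice donor and acceptor windows, coding
    consequence, a target intron interval), screens variants against a
    reference-panel allele-frequency catalogue with a one-sided Fisher
    exact enrichment test and poly-base and repeat-insertion exclusion
    rules, computes per-variant case-control statistics (minor-allele
    frequency, the exact conditional Hardy-Weinberg test, allelic Fisher
    exact test), performs a gene-level carrier burden chi-square test, and
    estimates two-locus haplotype frequencies from unphased genotypes by
    expectation-maximisation to derive D, D-prime, r-squared and LOD and to
    build solid-spine haplotype blocks. A seeded synthetic-data module
    generates cohorts, reference panels, gene models and annotation tracks
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
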