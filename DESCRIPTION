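Package: lofassoc
Title: Gene-Level Loss-of-Function Variant Association and Expression
    Analysis for Two-Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A reusable downstream-analysis pipeline for two-cohort
    (case/control or breed-vs-breed) sequencing studies.  Implements the
    variant quality-control cascade (call rate, minor allele frequency,
    exact Hardy-Weinberg tests), a single-variant Fisher exact scan with
    genomic-control lambda, gene-level loss-of-function variant
    enrichment via a collapsed allele-count chi-squared test with Woolf
    odds-ratio intervals together with Burden, SKAT and SKAT-O score
    tests, population-structure summaries (genotype PCA, identity-by-
    state neighbour-joining trees, observed heterozygosity), empirical
    Bayes moderated-t differential expression with an adaptive absolute
    log2-fold-change threshold, hypergeometric gene-set
    overrepresentation, and a Balding-Nichols study simulator that
    generates genotype and expression fixtures with planted effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
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
    tools,
    utils,
    vcfR
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
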