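Package: svcohort
Title: Consensus Structural Variant Calling and Population Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building a non-redundant population structural
    variant (SV) call set from per-sample output of two independent SV
    callers, and for the downstream cohort analyses commonly applied to
    such call sets in livestock resequencing studies. Within each sample,
    raw deletion, insertion, duplication and inversion calls are filtered
    by read-pair support and intersected between callers using an
    absolute 25 bp overlap merge rule; per-sample consensus calls are
    then merged across individuals into a cohort call set restricted to
    variants seen in two or more animals. On top of the call set the
    package computes breed- and group-specific SV sets and Venn
    partitions, principal component analysis of the carrier
    presence/absence matrix, gene-model based consequence classification
    with loss-of-function cataloguing, a chi-squared test for SV
    depletion in conserved genes, sliding-window SV density hotspot
    scanning, descriptive length/type/chromosome summaries, and per-locus
    diversity statistics (Ho, He, PIC, Ne) from biallelic genotype
    counts. A fully deterministic cohort simulator with truth
    bookkeeping supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
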