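Package: omixhub
Title: Multi-Omics Integration and Network Hub-Gene Discovery for Paired Tumor/Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates paired tumor/normal gene expression, miRNA expression,
    DNA methylation and segmented copy-number data to nominate key (hub) genes.
    Provides empirical-Bayes moderated paired differential testing with
    Benjamini-Hochberg control, gene-level five-state copy-number calling from
    SEG segments with a recurrence test, direction-aware (bimodal) filtering of
    differentially expressed genes against miRNA, methylation and copy-number
    alterations, protein-protein interaction subnetwork construction with
    degree/betweenness/closeness hub calling, hypergeometric gene-set
    enrichment, and a synthetic-cohort simulator with planted regulatory signal
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
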