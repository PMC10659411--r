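Package: gasderminevo
Title: Comparative Genomics of the Gasdermin Family: Discovery, Phylogeny,
    and Caspase Cleavage-Site Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully reproducible pipeline for comparative
    analysis of gasdermin-like protein families. Curates protein datasets
    (redundancy clustering, reciprocal-best-hit orthology, partial-sequence
    trimming), builds profile hidden Markov models from curated alignments
    and scans proteins or six-frame-translated contigs for family members,
    infers neighbor-joining phylogenies with monophyly tests, delimits the
    interdomain linker by projecting reference structural boundaries through
    an alignment, extracts and classifies candidate caspase cleavage
    tetrapeptides (P4..P1 windows ending at an aspartate), summarises them
    as sequence logos with small-sample-corrected information content and
    per-clade tables, and computes Kyte-Doolittle hydropathy profiles. A
    synthetic-data generator with full ground truth (species tree, domain
    architecture, planted clade-specific tetrapeptides, decoys) makes every
    stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
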