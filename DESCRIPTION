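Package: corofam
Title: Curation and Classification of Coronin Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for gene-structure-aware curation and
    classification of the coronin protein family. Maps intron positions and
    splice phases onto protein multiple alignments, validates splice
    junctions, flags suspicious exon borders by cross-species conservation,
    detects mutually exclusive exon clusters, applies completeness and
    pseudogene rules, scans for the coronin domain with position-specific
    scoring matrices, predicts oligomerization from the coiled-coil
    trimerization motif, assembles domain architectures, assigns coronin
    classes 1-4 from architecture plus monophyletic grouping in a reference
    tree, computes sequence-logo information content, and summarizes dataset
    statistics. Ships a deterministic simulator of coronin-like families
    with full ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    ape,
    phangorn,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
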