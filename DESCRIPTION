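Package: enhancerlink
Title: Linking Ligand-Activated Enhancers to Target Genes from Nascent
    Transcription and Chromatin Architecture Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for identifying the active enhancer
    network of a ligand-activated transcription factor in a differentiated
    cell type. From strand-specific nascent-transcription coverage the
    package calls transcript units and divergent (eRNA-producing)
    initiation sites, classifies transcription-factor binding sites into
    transcriptionally active and silent, detects ligand-induced changes in
    gene-body and enhancer transcription, links changing enhancers to the
    closest gene with changing expression, builds CTCF/cohesin co-peak
    boundaries and functional domains, and analyses chromosome-conformation
    interaction frequencies in fixed genomic bins. A synthetic-genome
    generator with planted ground truth makes every stage testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
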