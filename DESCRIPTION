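Package: estrocycle
Title: Multi-Tissue Estrous-Cycle Transcriptomics and Signature Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for multi-tissue estrous-cycle transcriptomics:
    differential-expression calling between cycle phases from pooled counts,
    trend-based tissue clustering by cosine similarity, gene-set
    over-representation against GMT collections, network-hubness testing on
    directed signaling networks, signed-regulon transcription-factor activity
    inference with a permutation null, and a transcriptomic-alteration-signature
    (TAS) comparative engine that matches log2 fold-change signatures by
    Spearman correlation and aggregates beneficial/deleterious outcome labels
    into phase-to-tissue specific protection (PTSP) calls. Includes a
    negative-binomial synthetic-data generator with planted ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
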