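Package: mirnetevo
Title: Evolutionary Analysis of miRNAs in a Signed TF-miRNA Regulatory Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systems-level analysis of microRNA evolution in a signed,
    tri-partite transcription-factor/miRNA/target regulatory network.
    Provides a validated signed edge-list data model with topology
    summaries, miRNA sequence-divergence estimation from pairwise
    genome-alignment blocks, sign-stratified coevolution statistics
    (Spearman correlation, median-split Wilcoxon comparisons,
    signal-preference and pathway co-regulation contingency tests with
    Fisher's exact test), shortest-path cascade ordering of regulators,
    link-perturbation sensitivity analysis, and a synthetic-data
    generator with planted statistical structure for end-to-end testing
    of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils,
    fgsea,
    rtracklayer,
    GenomicRanges,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
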