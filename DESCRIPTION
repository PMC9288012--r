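Package: syntarch
Title: Syntelog Detection and Promoter TFBS Architecture Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies putative stress-responsive syntelog genes across
    plant genomes and compares the transcription-factor-binding-site
    architectures of their promoters. Provides homolog detection (BLAST
    tabular parsing or an internal Smith-Waterman path), collinear block
    chaining, gene duplication classification (WGD/segmental, tandem,
    proximal, dispersed, singleton), strand-aware promoter extraction,
    position-weight-matrix scanning of promoters with a population
    Z-score filter, an alignment-free triplet-event distance between
    promoter architectures, neighbor-joining clustering of the resulting
    distance matrix, and a synthetic genome generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
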