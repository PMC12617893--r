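Package: zps
Title: Zero-Shot Protein Segmentation from Language-Model Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects boundaries of functional protein segments (folded
    domains, intrinsically disordered regions and sub-regions) from
    per-residue protein language-model embedding matrices using a
    sliding-window kernel change-point analysis, with no training or
    fine-tuning. Provides average-pooled segment embeddings and k-mer
    baseline embeddings, correction of over-segmentation by cosine or
    cluster merging, transfer of interval annotations onto segments under
    30-percent overlap rules, segmentation benchmarking by intersection
    over union and boundary distances, nearest-neighbour categorization
    with normalized confusion matrices and binomial confidence intervals,
    RGB colour rendering of segment embeddings, shuffle-based enrichment
    tests, graph-community clustering of unannotated segments, and a
    synthetic-fixture generator for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    uwot,
    optparse
Config/testthat/edition: 3
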