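Package: shieldscan
Title: Discovery of Anti-Phage Defense Systems from Protein Language-Model
    Embeddings and Genomic Context
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies prokaryotic genes as anti-phage defensive by encoding
    each gene as a fixed-length feature vector (mean-pooled protein
    language-model embeddings of a five-gene window concatenated with 119
    genomic-context features) and training a homology-fold-aware gradient
    boosting ensemble. Includes GenBank/GFF3 genome parsing, redundancy
    reduction by sequence clustering, leakage-free fold assignment,
    deduplicated precision-recall evaluation with cosine nearest-neighbour,
    signed best-hit and guilt-by-association baselines, and downstream
    genome analyses: transcriptional-unit calling, defense-island and
    mobile-element context frequencies, pangenome accumulation curves and
    validation-rate curves. A seeded synthetic-genome generator provides
    desk-scale test cohorts with planted GC, motif and island signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    igraph,
    methods,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
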