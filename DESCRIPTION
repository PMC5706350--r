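Package: tfcooc
Title: Proximity-Based Transcription Factor Co-Occurrence Graphs and Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds normalized transcription factor (TF) co-occurrence graphs
    from genomic binding-site coordinates (ChIP-seq peaks or motif matches),
    filters graph edges to an empirically calibrated false-positive rate using
    a permutation null, and partitions the filtered graph with a native
    implementation of the Markov Clustering Algorithm (MCL).  The unfiltered
    signed graph is reused to score and filter putative TF binding sites
    (precision/recall/F-score sweeps) and to evaluate predicted TF-TF
    interactions against a reference protein-protein interaction table and
    against motif-similarity scores.  Includes seeded synthetic-data
    generators (planted co-binding clusters, independent-binding null,
    true/decoy putative-site fixtures) so every stage can be exercised and
    calibrated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
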