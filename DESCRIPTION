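Package: ctcfgrammar
Title: Orientation Grammar of CTCF Binding Sites and TAD Boundary Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of the orientation "grammar" of CTCF binding sites along
    chromosome arms: classification and counting of orientation k-plets
    (Same, Convergent, Divergent, Convergent+Divergent), chi-square and
    orientation-randomization tests against theoretical class proportions,
    distance-window clustering with per-pattern enrichment maps, ChIP-seq /
    motif / rank-aggregate site scoring, a permeability-based loop-extrusion
    simulator evaluated against reference loop catalogs, a multi-dataset TAD
    boundary consensus algorithm with conservation scores based on Louvain
    community detection, and TAD anatomy profiling around boundaries and
    directionality-index inversion points. Includes synthetic-data generators
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    limma,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
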