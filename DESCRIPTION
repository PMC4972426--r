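Package: climpr
Title: Motif Clustering on Similarity Graphs via Per-Node Maximal Cliques
Version: 1.0.0
Authors@R:
    person("climpr", "maintainers", email = "climpr@example.org",
           role = c("aut", "cre"))
Description: Clusters transcription-factor binding-site motifs by building a
    weighted motif similarity graph and applying the CLIMP algorithm: a greedy
    per-node maximal-clique search, ranked clique merging under overlap and
    adjacency thresholds, redundant-node resolution, and edge-weight ranking
    of the resulting clusters.  Includes an information-content weighted
    (SPIC-style) motif similarity metric over position frequency and weight
    matrices, Adjusted Rand Index evaluation utilities, synthetic sub-motif
    and planted-partition generators for benchmarking, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    withr,
    parallel,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
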