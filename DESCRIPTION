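Package: rwrfuse
Title: Multi-Omics Data Integration by Random Walk with Restart on
    Multiplex Sample Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses two or more per-omics sample-similarity networks into a
    single integrated patient network by random walk with restart (RWR) on a
    multiplex network, either with identity inter-layer coupling (RWRF) or
    with weighted directed neighbor coupling (RWRNF).  Includes the
    scaled-exponential-kernel similarity measure, preprocessing for
    feature-by-sample omics matrices, spectral clustering of the fused
    network with cluster-number recommendation by seven-validity-index
    voting, evaluation statistics (Dunn index, normalized mutual
    information, log-rank test), NMI-based per-feature ranking, and
    synthetic-data generators for benchmarking noise robustness of the
    fusion step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
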