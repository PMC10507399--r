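Package: cytosweep
Title: Checkpointed Clustering of Cytometry Data with Grid-Resolution
    Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A checkpointed analysis pipeline for high-dimensional cytometry
    event tables (mass cytometry, spectral flow, or multiplexed imaging
    intensity tables). Reads FCS files or pre-corrected expression matrices
    together with file-, marker- and run-level metadata, applies the arcsinh
    transformation, computes a UMAP embedding, partitions events with an
    online self-organizing map (with optional metaclustering) or with CLARA
    k-medoids, sweeps a series of SOM grid sizes scored by the
    Davies-Bouldin index to choose a cluster resolution, summarizes clusters
    (frequencies and median expression), assigns clusters to gated landmark
    populations by cosine similarity, and evaluates per-cell cluster
    annotations against ground-truth labels with accuracy, adjusted Rand
    index, Fowlkes-Mallows index and mutual information. Includes a seeded
    synthetic-data generator with known population structure for testing
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    grDevices,
    jsonlite,
    pheatmap,
    stats,
    tools,
    utils,
    uwot,
    yaml
LinkingTo:
    Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
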