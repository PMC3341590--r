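Package: exprSOM
Title: Multi-Experiment Gene Expression Mapping with Self-Organizing Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters gene-by-condition expression matrices drawn from
    multiple heterogeneous experiments onto a two-dimensional
    self-organizing map using a Pearson-correlation similarity that
    tolerates missing values. Provides median-shift normalization of
    per-gene profiles within experiment blocks, per-node Gene Ontology
    over-representation analysis (Fisher's exact test with
    Benjamini-Hochberg correction), an empirical sampling test for
    spatial non-randomness of gene sets on the map, co-clustering
    reproducibility assessment across independently seeded maps,
    threshold-based region selection and gene-category overlays, and a
    seeded synthetic-data generator with known planted structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
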