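Package: synaxon
Title: Synthesis of Brain-Wide Long-Range Axonal Morphologies and Their Connectome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters reconstructed long-range axons by their inter-regional
    projection patterns with per-source-region Gaussian mixture models
    (expectation-maximization with BIC model selection), then synthesizes new
    axons inside a voxelized brain atlas: probabilistic target-region choice,
    weighted Steiner-tree trunks that preferentially follow fiber tracts, and
    topological (persistence-barcode driven) tuft growth at the target points.
    Derives single-cell and region-level axo-dendritic connectivity from the
    synthesized population by spatial proximity, and provides the statistical
    validation machinery (feature normalization, maximum-visible-spread
    scores, projection ratios) together with toy-atlas and synthetic-population
    generators so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    Matrix,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
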