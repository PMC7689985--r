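Package: cginet
Type: Package
Title: Multi-Relational Graph Convolutional Prediction of Chemical-Gene Interactions
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts typed chemical-gene interactions (e.g.
    "decreases^activity") by link prediction in an integrated heterogeneous
    graph of chemicals, genes and pathways. Implements the CGINet family of
    models: a two-layer relational graph convolutional encoder (whole-graph or
    two-stage subgraph perspective), augmentation of the interaction subgraph
    with latent links mined from S-G and S-G-P network substructures, and a
    DEDICOM tensor-decomposition decoder. Training uses degree-biased negative
    sampling and a margin (hinge) ranking loss optimized end-to-end with Adam.
    Includes a synthetic-graph generator with planted substructure signal, so
    the full pipeline is exercisable without external databases, plus
    per-interaction-type evaluation (AUROC, AUPRC, AP@k) and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
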