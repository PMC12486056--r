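Package: spathgt
Title: Hierarchical Graph Transformer Embeddings for Spatial Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised hierarchical embeddings for single-cell spatial
    transcriptomics and proteomics. Tissues are modelled as a two-level graph:
    a Voronoi-adjacency spatial graph over cells and, inside each cell, the
    mutual-information gene co-expression network of its cell type. A stack of
    intra-level graph-transformer layers coupled by directional cross-level
    message passing is pretrained with spatially-aware contrastive, masked
    auto-encoding and orthogonality objectives, yielding cell and per-cell gene
    embeddings for clustering, annotation, tissue-level classification and gene
    imputation. Includes a synthetic-tissue generator with planted cell types,
    spatial niches and co-expression modules so every stage can be tested
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    deldir,
    FNN,
    igraph,
    nnet,
    pROC,
    jsonlite,
    yaml,
    rlang,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
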