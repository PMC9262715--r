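Package: cortexprox
Title: Cell Composition, Laminar Organization and Soma-Proximity Statistics
    for Spatial Cell Atlases of the Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical analysis of spatially resolved single-cell atlases of
    the cerebral cortex, built around imaging-based transcriptomics (e.g.
    MERFISH) cell tables: cell-type composition and headline ratios
    (glia:neuron, excitatory:inhibitory), cortical-depth profiles and
    depth-resolved E:I curves, soma contact/proximity graphs with a
    density-preserving label-permutation null for pairwise enrichment,
    nearest-neighbor self/other tests, blood-vessel detection with glial
    adjacency counts, multiway neuron-oligodendrocyte contact statistics,
    GAD1-positive OPC classification, depth-dependent microglia-IT contact
    trends, and contact-conditioned ligand-receptor enrichment. Includes a
    fully parameterized synthetic cortical-tissue generator (hard-core point
    process, laminar layers, satellite-cell and vessel injections,
    negative-binomial expression) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
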