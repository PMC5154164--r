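Package: pathcollage
Title: Automated Layout, Assembly and Omics Overlay of Multi-Pathway
    Metabolic Diagrams
Version: 1.0.0
Authors@R:
    person("Sam", "Ortega", email = "sortega@example.org", role = c("aut", "cre"))
Description: Builds personalized multi-pathway metabolic diagrams
    ("pathway collages") from a pathway collection: topology-aware
    automatic layout of individual pathways (linear chains, anchored
    circles for cycles, layered trees for branched pathways), shelf-packed
    assembly of many pathways grouped by functional class, inter-pathway
    metabolite connection edges and node merging, overlay of gene
    expression, metabolomics or reaction-flux data as single-value
    coloring or time-series box grids, semantic-zoom rendering to SVG and
    PNG, and JSON interchange including a Cytoscape-style viewer export.
    A deterministic fixture generator produces synthetic pathway
    collections and omics tables so the full pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
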