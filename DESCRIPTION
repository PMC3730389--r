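Package: acunet
Title: Co-Occurrence Network Analysis of Acupoint Prescriptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and analyses acupoint co-occurrence networks from binary
    study-by-acupoint incidence data, as used to study acupoint combination
    patterns in clinical acupuncture trials (e.g. for low back pain). A
    pointwise mutual-information statistic scores every acupoint pair; the
    resulting matrix is binarized across a fine threshold grid under full
    connectivity and edge-density constraints; degree and Brandes betweenness
    centralities, Newman-Girvan modularity, and seeded greedy module
    detection with Kernighan-Lin refinement characterise the selected
    network. Includes a planted prescription-module generator for recovery
    benchmarks, a constrained fixture builder that reconstructs incidence
    data from published marginal and pairwise usage counts, and exports
    (CSV, edge list, GraphML) for visualization tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
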