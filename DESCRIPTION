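Package: ipcacmi
Title: Gene Regulatory Network Inference by Conditional Mutual Information
    and MIT-Scored Hill Climbing
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Learns the structure of gene regulatory networks from
    expression matrices. Implements the path-consistency algorithm based on
    conditional mutual information (PCA-CMI), which prunes a complete graph
    by order-increasing Gaussian CMI tests over common-neighbour
    conditioning sets, and its hybrid extension IPCA-CMI, which interleaves
    the pruning with hill-climbing edge orientation under the mutual
    information test (MIT) score and draws conditioning sets from
    blocked-path-weighted neighbourhoods of either endpoint. Includes
    equal-width and equal-frequency discretization, skeleton evaluation
    metrics (accuracy, F-score, Matthews correlation, subgraph-selection
    probabilities), a seeded linear-Gaussian structural-equation simulator
    for benchmark-shaped data, and readers and writers for expression and
    gold-standard edge-list files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    SummarizedExperiment
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, GeneExpression, Bayesian
RoxygenNote: 7.3.3
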