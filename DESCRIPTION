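Package: lapgsa
Title: Gene Set Generation from Metabolic Network Laplacian PCA and Max-Mean Gene Set Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates semi-exhaustive, overlapping gene sets from the
    principal component analysis of the Laplacian matrix of a metabolic
    network (a gene-reaction-compound tripartite graph), runs two-class
    unpaired max-mean gene set analysis with a permutation null and
    plug-in FDR, applies a hypergeometric (two-tailed Fisher) enrichment
    test to separate driver from passenger genes, and reconstructs
    pathway-centric context graphs for visualisation. Includes KGML and
    edge-list network readers, GMT set input/output, GraphML/SIF
    exporters, set-collection analytics, and a ground-truthed synthetic
    data generator with planted differentially expressed subnetworks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    igraph,
    xml2,
    withr,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
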