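Package: corgraph
Title: Correlation Graphs, Transform Stacks, Clustering and Layout for
    Tabular Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless toolkit for turning numeric tables into weighted
    correlation graphs and analysing them: all-vs-all Pearson/Spearman
    correlation with thresholded graph construction, a composable stack of
    graph transforms (k-nearest-neighbour edge pruning, edge/node filters,
    small-component removal, edge contraction), Markov (MCL) and Louvain
    clustering with a single granularity knob each, node and edge analytics
    (PageRank, betweenness, eccentricity, degree), seeded force-directed
    layout in two or three dimensions with concentric large-to-small
    component arrangement, and attribute-to-visual colour/size encodings.
    Graphs are read and written as GML, GraphML, JSON graph, weighted edge
    lists and symmetric adjacency matrices.  Synthetic planted-structure
    generators provide ground-truthed test data for every step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
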