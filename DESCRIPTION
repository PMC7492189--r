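Package: neurocult
Title: Reconstruction and Network Analysis of Growing Neuronal Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the network architecture of growing neuronal
    cultures imaged by label-free quantitative phase microscopy. Provides a
    synthetic-culture generator (ground-truth spatial networks rendered as
    microscopy-like snapshots with controllable corruption), reconstruction of
    spatial graphs from images (soma segmentation, skeleton terminal detection,
    gap filling, steerable-filter neurite tracing), network statistics
    (degree/closeness/betweenness centrality, node-to-node degree mixing,
    assortativity, transitivity, local and square clustering, edge-length
    exceedance), comparison against six null-model families (random regular,
    Erdos-Renyi, Watts-Strogatz, Barabasi-Albert, spatial scale-free, weighted
    multifractal graph), and multifractal spectrum estimation by finite box
    covering with a Legendre transform. A pipeline orchestrates all stages
    reproducibly from a single YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    igraph,
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
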