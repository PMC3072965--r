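Package: hiermap
Title: Hierarchical Map Equation for Multilevel Community Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Flow-based multilevel community detection for weighted, directed or
    undirected networks. Implements the hierarchical map equation, an
    information-theoretic objective that scores a nested partition of a network
    by the per-step description length (in bits) of a random walker, together
    with a recursive stochastic search that minimizes it, teleportation-excluded
    flow computation for directed networks, a three-level benchmark-network
    generator with its analytic feasibility region, normalized mutual
    information for partition comparison, and readers/writers for edge-list,
    Pajek and tree-file formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
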