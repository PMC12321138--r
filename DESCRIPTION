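Package: hypercoop
Title: Evolutionary Public Goods Games on Hypergraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the evolution of cooperation in public goods games played
    on hypergraphs, where groups of any size interact through shared
    hyperedges. Implements five higher-order strategy-update mechanisms
    (higher-order death-birth, higher-order imitation, group-mutual
    comparison, group-inner comparison, and higher-order pair comparison),
    seeded Monte Carlo and exact absorbing-Markov-chain computation of
    fixation probabilities under weak selection, higher-order random walks,
    and closed-form critical synergy factors computed from hypergraph
    structure (mean hyperdegree and order, their heterogeneities,
    hyperdegree-order assortativity, and hyperedge overlap strength).
    Includes generators for homogeneous hypergraph families with controlled
    overlap and a configuration model with prescribed hyperdegree and order
    sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
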