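Package: netblocks
Title: Building Blocks of Networks: Motif-Preserving Sampling and Diffusion Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts small subgraphs ("building blocks") of undirected networks
    that preserve both the motif distribution and the susceptible-infected (SI)
    diffusion dynamics of the host graph. Implements eleven subgraph sampling
    techniques (node-, edge-, exploration- and random-walk-based, including
    non-backtracking and Metropolis-Hastings walks), an ESU census of connected
    k-node subgraphs with isomorphism classification and shuffle-greedy
    edge-/node-disjoint selection, discrete-time SI simulation with
    transient-time estimation and logistic conductance fitting, a boosted
    regression protocol that predicts host transient time from sample motif
    features, a synthetic generator of interest-network corpora with target
    density, clustering and degree assortativity, and an end-to-end pipeline
    that ranks sampling methods and recommends a sample size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    xgboost,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
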