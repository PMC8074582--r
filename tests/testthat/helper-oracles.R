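# Independent brute-force oracles used against the package's own
# implementations. These deliberately avoid the package's code paths:
# connectivity and isomorphism come from igraph, subsets from combn.

# All connected k-node induced subgraphs by testing every C(n, k) subset.
brute_connected_subgraphs <- function(g, k) {
  nm <- sort(igraph::V(g)$name)
  subsets <- combn(nm, k)
  keep <- apply(subsets, 2, function(s) {
    igraph::is_connected(igraph::induced_subgraph(g, s))
  })
  found <- subsets[, keep, drop = FALSE]
  # rows sorted within each occurrence, occurrences sorted for comparison
  occ <- apply(found, 2, function(s) paste(sort(s), collapse = "|"))
  sort(occ)
}

# Number of isomorphism classes among all connected labelled graphs on k
# nodes, grouped with igraph's isomorphism test.
brute_class_count <- function(k) {
  nb <- k * (k - 1) / 2
  pairs <- t(combn(k, 2))
  reps <- list()
  for (code in 0:(2^nb - 1)) {
    sel <- bitwAnd(bitwShiftR(code, 0:(nb - 1)), 1L) == 1L
    g <- igraph::make_empty_graph(k, directed = FALSE)
    if (any(sel)) g <- igraph::add_edges(g, t(pairs[sel, , drop = FALSE]))
    if (!igraph::is_connected(g)) next
    new <- TRUE
    for (r in reps) if (igraph::isomorphic(r, g)) { new <- FALSE; break }
    if (new) reps[[length(reps) + 1]] <- g
  }
  length(reps)
}

# Random Erdos-Renyi graph with character vertex names.
er_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

# Occurrence string keys for a motif_occurrences object, comparable with
# brute_connected_subgraphs output.
occ_keys <- function(occ) {
  nodes <- occurrence_nodes(occ)
  sort(apply(nodes, 1, function(s) paste(sort(s), collapse = "|")))
}

expect_subgraph_of <- function(sample_g, host_g) {
  expect_true(all(igraph::V(sample_g)$name %in% igraph::V(host_g)$name))
  if (igraph::ecount(sample_g) > 0) {
    el_s <- igraph::as_edgelist(sample_g)
    key <- function(el) paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el_h <- igraph::as_edgelist(host_g)
    expect_true(all(key(el_s) %in% key(el_h)))
  }
}
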