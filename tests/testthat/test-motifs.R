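fx <- fixture_graphs()

test_that("connected isomorphism class counts are 2, 6, 21 for k = 3, 4, 5", {
  expect_equal(nrow(motif_class_table(3)), 2)
  expect_equal(nrow(motif_class_table(4)), 6)
  expect_equal(nrow(motif_class_table(5)), 21)
  expect_error(motif_class_table(6), "k must be")
})

test_that("canonical classes agree with igraph's isomorphism grouping", {
  # brute force over all labelled graphs on 4 nodes: same partition
  for (k in 3:4) {
    expect_equal(nrow(motif_class_table(k)), brute_class_count(k))
  }
  # same labelled path in three labellings -> one class
  mk <- function(perm) {
    A <- matrix(0L, 3, 3)
    A[perm[1], perm[2]] <- A[perm[2], perm[1]] <- 1L
    A[perm[2], perm[3]] <- A[perm[3], perm[2]] <- 1L
    A
  }
  ids <- vapply(list(c(1, 2, 3), c(2, 1, 3), c(3, 1, 2)),
                function(p) canonical_class(mk(p))$canon, 0L)
  expect_equal(length(unique(ids)), 1)
  expect_error(canonical_class(matrix(0L, 3, 3)), "connected")
})

test_that("ESU matches brute-force subset enumeration on fixtures", {
  occ <- enumerate_connected_subgraphs(fx$triangle, 3)
  expect_equal(nrow(occ$nodes_idx), 1)

  occ <- enumerate_connected_subgraphs(fx$K4, 3)
  expect_equal(nrow(occ$nodes_idx), 4)
  expect_equal(length(unique(occ$canon)), 1) # all triangles

  # star hub+3 leaves: 3 path occurrences, the all-leaves triple is disconnected
  star4 <- induced_on(fx$star10, c("1", "2", "3", "4"))
  occ <- enumerate_connected_subgraphs(star4, 3)
  expect_equal(nrow(occ$nodes_idx), 3)
  tri_canon <- canonical_class(matrix(1L, 3, 3) - diag(3L))$canon
  expect_true(all(occ$canon != tri_canon))
})

test_that("ESU equals the brute-force oracle on random graphs", {
  set.seed(17)
  cases <- expand.grid(rep = 1:3, p = c(0.2, 0.4, 0.6), k = 3:4)
  for (i in seq_len(nrow(cases))) {
    g <- er_graph(10, cases$p[i], 5000 + i)
    k <- cases$k[i]
    expect_equal(occ_keys(enumerate_connected_subgraphs(g, k)),
                 brute_connected_subgraphs(g, k),
                 label = sprintf("p=%.1f k=%d", cases$p[i], k))
  }
})

test_that("joint tallies are invariant under node relabelling", {
  g <- er_graph(14, 0.3, 99)
  cen1 <- build_census(g, 4, seed = 1)
  set.seed(2)
  perm <- sample(igraph::V(g)$name)
  g2 <- g
  igraph::V(g2)$name <- perm
  cen2 <- build_census(g2, 4, seed = 1)
  expect_equal(cen1$joint_counts, cen2$joint_counts)
})

test_that("joint counts agree with igraph's motif census", {
  # independent oracle: igraph::motifs counts per isomorphism class
  for (sd in 1:3) {
    g <- er_graph(20, 0.25, 700 + sd)
    cen <- build_census(g, 3, seed = 1)
    m <- igraph::motifs(g, 3) # positions 3 (path) and 4 (triangle)
    expect_equal(sort(as.integer(cen$joint_counts)),
                 sort(as.integer(m[c(3, 4)])))
    expect_equal(cen$total_joint, sum(m, na.rm = TRUE))
  }
})

test_that("greedy disjoint selection honours the overlap policy", {
  bt <- fx$two_triangles_shared_node
  occ <- enumerate_connected_subgraphs(bt, 3)
  # restrict to the two triangle occurrences: they share one node, so
  # node-disjoint keeps exactly one and edge-disjoint keeps both
  tri_canon <- canonical_class(matrix(1L, 3, 3) - diag(3L))$canon
  sel <- occ$canon == tri_canon
  occ_tri <- occ
  occ_tri$nodes_idx <- occ$nodes_idx[sel, , drop = FALSE]
  occ_tri$canon <- occ$canon[sel]
  expect_equal(nrow(occ_tri$nodes_idx), 2)
  for (sd in 1:10) {
    expect_equal(sum(greedy_disjoint_set(occ_tri, bt, "NODE_DISJOINT", sd)), 1)
    expect_equal(sum(greedy_disjoint_set(occ_tri, bt, "EDGE_DISJOINT", sd)), 2)
  }
})

test_that("K4 triangle census is 4 joint / 1 edge-disjoint for every seed", {
  for (sd in 1:20) {
    cen <- build_census(fx$K4, 3, "EDGE_DISJOINT", seed = sd)
    tri <- names(cen$joint_counts)[cen$joint_counts > 0]
    expect_equal(as.integer(cen$joint_counts[tri]), 4)
    expect_equal(as.integer(cen$disjoint_counts[tri]), 1)
  }
})

test_that("kept occurrences are mutually disjoint and maximal", {
  for (sd in 1:5) {
    g <- er_graph(15, 0.3, 40 + sd)
    occ <- enumerate_connected_subgraphs(g, 3)
    nodes <- occurrence_nodes(occ)
    for (policy in c("EDGE_DISJOINT", "NODE_DISJOINT")) {
      keep <- greedy_disjoint_set(occ, g, policy, seed = sd)
      kept <- which(keep)
      overlap <- function(i, j) {
        shared <- intersect(nodes[i, ], nodes[j, ])
        if (policy == "NODE_DISJOINT") return(length(shared) > 0)
        if (length(shared) < 2) return(FALSE)
        # induced occurrences share an edge iff the shared node set spans one
        igraph::ecount(igraph::induced_subgraph(g, shared)) > 0
      }
      # pairwise disjointness among kept
      if (length(kept) > 1) {
        pairs <- combn(kept, 2)
        for (c_ in seq_len(ncol(pairs)))
          expect_false(overlap(pairs[1, c_], pairs[2, c_]))
      }
      # maximality: every discarded occurrence overlaps a kept one
      for (i in which(!keep))
        expect_true(any(vapply(kept, function(j) overlap(i, j), TRUE)))
    }
  }
})

test_that("F1 >= F2 >= F3 on random graphs", {
  # per class the joint count always dominates; across policies the
  # ordering is guaranteed by the heuristic at the total level (a
  # node-disjoint set is in particular edge-disjoint)
  for (sd in 1:20) {
    g <- er_graph(14, 0.35, 300 + sd)
    c_edge <- build_census(g, 3, "EDGE_DISJOINT", seed = sd)
    c_node <- build_census(g, 3, "NODE_DISJOINT", seed = sd)
    expect_true(all(c_edge$joint_counts >= c_edge$disjoint_counts))
    expect_true(all(c_node$joint_counts >= c_node$disjoint_counts))
    expect_gte(c_edge$total_disjoint, c_node$total_disjoint)
  }
})

test_that("disjoint totals are stable across MIS seeds", {
  set.seed(8)
  for (i in 1:20) {
    g <- er_graph(30, 0.25, 6000 + i)
    totals <- vapply(1:10, function(sd)
      build_census(g, 3, seed = sd)$total_disjoint, 0)
    rel_range <- diff(range(totals)) / max(totals)
    expect_lte(rel_range, 0.20)
  }
})

test_that("frequency variants normalize as specified", {
  fx <- fixture_graphs()
  cen <- build_census(fx$triangle, 3)
  jr <- motif_frequencies(cen, "JOINT_RATIO")
  expect_equal(sum(jr), 1)
  expect_equal(as.numeric(jr[cen$joint_counts > 0]), 1)
  expect_equal(motif_frequencies(cen, "DISJOINT_TOTAL_RATIO"), 1)

  cen <- build_census(fx$K4, 3, "EDGE_DISJOINT", seed = 3)
  dr <- motif_frequencies(cen, "DISJOINT_RATIO")
  expect_equal(as.numeric(dr[cen$joint_counts > 0]), 0.25)
  expect_equal(motif_frequencies(cen, "DISJOINT_TOTAL_RATIO"), 0.25)

  # graph with no edges: zero counts, zero frequencies, warning
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(g0)$name <- as.character(1:5)
  cen0 <- build_census(g0, 3)
  expect_equal(cen0$total_joint, 0)
  expect_warning(fr <- motif_frequencies(cen0, "JOINT_RATIO"), "no motif")
  expect_equal(sum(fr), 0)
})

test_that("census export writes a readable CSV with a JSON sidecar", {
  d <- withr::local_tempdir()
  cen <- build_census(fx$K4, 3, seed = 2)
  path <- file.path(d, "census.csv")
  write_census(cen, path)
  df <- read.csv(path, colClasses = c(class_canon = "character"))
  expect_equal(nrow(df), 2)
  expect_equal(sum(df$joint_count), 4)
  side <- jsonlite::read_json(file.path(d, "census.json"))
  expect_equal(side$mis_seed, 2)
  expect_equal(side$total_joint, 4)
})
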