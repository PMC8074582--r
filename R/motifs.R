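#' Motif isomorphism classes of connected k-node graphs
#'
#' A motif class is identified by the canonical form of its adjacency
#' matrix: the upper-triangular bit string (pairs in row-major order)
#' minimized over all k! node permutations, encoded as an integer. There
#' are exactly 2 connected classes for k = 3, 6 for k = 4 and 21 for
#' k = 5.
#'
#' @param k motif size, 3 to 5
#' @return data.frame with columns `canon` (canonical integer code),
#'   `n_edges`, and `label` (bit-string form), one row per connected class,
#'   ordered by canonical code; this ordering fixes the feature layout used
#'   throughout the package
#' @export
motif_class_table <- function(k) {
  check_motif_k(k)
  map <- canon_map_for_k(k)
  canon <- sort(unique(map[map >= 0]))
  data.frame(
    canon = canon,
    n_edges = vapply(canon, function(c) sum(bits_of(c, k * (k - 1) / 2)), 0L),
    label = vapply(canon, function(c)
      paste(bits_of(c, k * (k - 1) / 2), collapse = ""), ""),
    stringsAsFactors = FALSE)
}

check_motif_k <- function(k) {
  if (!(k %in% 3:5)) stop("motif size k must be 3, 4 or 5")
  invisible(k)
}

bits_of <- function(code, nbits) {
  as.integer(bitwAnd(bitwShiftR(code, 0:(nbits - 1)), 1L))
}

perms_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1)))
  }
  out
}

pair_index <- function(i, j, k) { # 1-based i < j, matching the C++ layout
  (i - 1) * (2 * k - i) / 2 + (j - i)
}

code_of_adjacency <- function(A) {
  k <- nrow(A)
  code <- 0L
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    if (A[i, j] != 0) code <- code + bitwShiftL(1L, pair_index(i, j, k) - 1L)
  code
}

adjacency_of_code <- function(code, k) {
  A <- matrix(0L, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    if (bitwAnd(bitwShiftR(code, pair_index(i, j, k) - 1L), 1L) == 1L)
      A[i, j] <- A[j, i] <- 1L
  A
}

code_connected <- function(code, k) {
  A <- adjacency_of_code(code, k)
  reach <- logical(k); reach[1] <- TRUE
  repeat {
    new <- reach | (A %*% reach > 0)
    if (all(new == reach)) break
    reach <- as.logical(new)
  }
  all(reach)
}

# Vector mapping every adjacency code (0 .. 2^C(k,2)-1) to the canonical
# code of its isomorphism class, or -1 for disconnected codes. Cached.
canon_map_for_k <- function(k) {
  key <- paste0("canon", k)
  if (!is.null(.netblocks_env[[key]])) return(.netblocks_env[[key]])
  nb <- k * (k - 1) / 2
  P <- perms_of(k)
  ncodes <- bitwShiftL(1L, nb)
  map <- rep(-1L, ncodes)
  for (code in 0:(ncodes - 1)) {
    if (!code_connected(code, k)) next
    A <- adjacency_of_code(code, k)
    best <- NA_integer_
    for (r in seq_len(nrow(P))) {
      Ap <- A[P[r, ], P[r, ]]
      c2 <- code_of_adjacency(Ap)
      if (is.na(best) || c2 < best) best <- c2
    }
    map[code + 1] <- best
  }
  .netblocks_env[[key]] <- map
  map
}

#' Canonical isomorphism class of a small connected graph
#'
#' @param A symmetric 0/1 adjacency matrix of a connected graph on 3-5 nodes
#' @return a list of class `motif_class_id` with fields `k` and `canon`
#'   (two graphs receive the same `canon` iff they are isomorphic)
#' @export
canonical_class <- function(A) {
  k <- nrow(A)
  check_motif_k(k)
  code <- code_of_adjacency(A)
  if (!code_connected(code, k)) stop("canonical_class requires a connected graph")
  structure(list(k = k, canon = canon_map_for_k(k)[code + 1]),
            class = "motif_class_id")
}

#' Enumerate all connected k-node induced subgraphs (ESU)
#'
#' ESU tree enumeration: each partial subgraph is extended only with
#' exclusive neighbours whose index exceeds the root's, so every connected
#' k-node induced subgraph is visited exactly once. Each occurrence carries
#' its canonical motif class.
#'
#' @param g undirected simple graph with at least k nodes
#' @param k motif size in 3..5
#' @return list of class `motif_occurrences`: `nodes` (matrix of vertex
#'   names, one sorted row per occurrence), `canon` (canonical code per
#'   occurrence), `k`, and `vertex_names` of the host
#' @export
enumerate_connected_subgraphs <- function(g, k) {
  check_motif_k(k)
  if (igraph::vcount(g) < k) stop("graph has fewer than k nodes")
  adj <- adjacency_list_int(g)
  res <- esu_enumerate_cpp(adj, as.integer(k), canon_map_for_k(k))
  nm <- igraph::V(g)$name
  structure(list(nodes_idx = res$nodes, canon = res$canon, k = k,
                 vertex_names = nm),
            class = "motif_occurrences")
}

#' @export
print.motif_occurrences <- function(x, ...) {
  cat(sprintf("motif_occurrences: %d connected %d-node subgraphs, %d classes present\n",
              nrow(x$nodes_idx), x$k, length(unique(x$canon))))
  invisible(x)
}

#' Occurrence node sets as vertex names
#'
#' @param occ a `motif_occurrences` object
#' @return character matrix, one row per occurrence
#' @export
occurrence_nodes <- function(occ) {
  matrix(occ$vertex_names[occ$nodes_idx], nrow = nrow(occ$nodes_idx))
}

#' Shuffle-greedy disjoint motif selection
#'
#' Approximates the maximum independent set of the occurrence overlap
#' graph: occurrences are shuffled by a seeded RNG and each is kept iff it
#' shares no edge (`EDGE_DISJOINT`) or no node (`NODE_DISJOINT`) with any
#' occurrence kept before it. The result is a maximal independent set.
#'
#' @param occ occurrences from [enumerate_connected_subgraphs()]
#' @param g the host graph the occurrences came from
#' @param policy `"EDGE_DISJOINT"` or `"NODE_DISJOINT"`
#' @param seed shuffle seed
#' @return logical keep-flag vector over the occurrences
#' @export
greedy_disjoint_set <- function(occ, g,
                                policy = c("EDGE_DISJOINT", "NODE_DISJOINT"),
                                seed = 1L) {
  policy <- match.arg(policy)
  m <- nrow(occ$nodes_idx)
  if (m == 0) return(logical(0))
  set.seed(seed)
  ord <- sample.int(m)
  mis_filter_cpp(occ$nodes_idx, ord, adjacency_list_int(g),
                 if (policy == "EDGE_DISJOINT") 1L else 2L)
}

#' Full motif census of a graph
#'
#' Joint (overlap-allowed, F1-style) per-class occurrence counts from ESU
#' enumeration, and disjoint counts after shuffle-greedy independent-set
#' selection (F2 for edge-disjoint, F3 for node-disjoint).
#'
#' @param g undirected simple graph
#' @param k motif size in 3..5 (default 4)
#' @param policy overlap policy for the disjoint counts
#' @param seed MIS shuffle seed (recorded in the census)
#' @return a list of class `motif_census` with `joint_counts` and
#'   `disjoint_counts` (named by canonical class code, fixed class
#'   ordering), `total_joint`, `total_disjoint`, `k`, `overlap_policy`,
#'   `mis_seed`
#' @export
build_census <- function(g, k = 4,
                         policy = c("EDGE_DISJOINT", "NODE_DISJOINT"),
                         seed = 1L) {
  policy <- match.arg(policy)
  check_motif_k(k)
  classes <- motif_class_table(k)
  zero <- setNames(integer(nrow(classes)), classes$canon)
  if (igraph::vcount(g) < k) {
    occ_canon <- integer(0); kept_canon <- integer(0)
  } else {
    occ <- enumerate_connected_subgraphs(g, k)
    occ_canon <- occ$canon
    kept_canon <- occ$canon[greedy_disjoint_set(occ, g, policy, seed)]
  }
  tally <- function(canon) {
    t <- table(factor(as.character(canon), levels = names(zero)))
    setNames(as.integer(t), names(zero))
  }
  joint <- tally(occ_canon)
  disjoint <- tally(kept_canon)
  structure(list(k = k, joint_counts = joint, disjoint_counts = disjoint,
                 overlap_policy = policy, total_joint = sum(joint),
                 total_disjoint = sum(disjoint), mis_seed = as.integer(seed)),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat(sprintf("motif_census (k=%d, %s, seed %d): %d joint, %d disjoint\n",
              x$k, x$overlap_policy, x$mis_seed, x$total_joint,
              x$total_disjoint))
  print(rbind(joint = x$joint_counts, disjoint = x$disjoint_counts))
  invisible(x)
}

#' Motif frequency variants
#'
#' Three normalizations of a census: `JOINT_RATIO` - each class's joint
#' count over the total joint count; `DISJOINT_RATIO` - each class's
#' disjoint count over the total *joint* count (the denominator is all
#' motifs of that size); `DISJOINT_TOTAL_RATIO` - the scalar ratio of all
#' disjoint motifs to all motifs of the size. An all-zero census yields an
#' all-zero result with a warning.
#'
#' @param census a [build_census()] result
#' @param variant one of the three variants
#' @return named numeric vector over classes, or a scalar for
#'   `DISJOINT_TOTAL_RATIO`
#' @export
motif_frequencies <- function(census,
                              variant = c("JOINT_RATIO", "DISJOINT_RATIO",
                                          "DISJOINT_TOTAL_RATIO")) {
  variant <- match.arg(variant)
  if (census$total_joint == 0) {
    warning("census has no motif occurrences; returning zeros")
    if (variant == "DISJOINT_TOTAL_RATIO") return(0)
    return(setNames(numeric(length(census$joint_counts)),
                    names(census$joint_counts)))
  }
  switch(variant,
    JOINT_RATIO = census$joint_counts / census$total_joint,
    DISJOINT_RATIO = census$disjoint_counts / census$total_joint,
    DISJOINT_TOTAL_RATIO = census$total_disjoint / census$total_joint)
}

#' Export a census as CSV (plus a JSON sidecar)
#'
#' @param census a [build_census()] result
#' @param path CSV path; a `.json` sidecar with policy, seed and totals is
#'   written next to it
#' @return `path`, invisibly
#' @export
write_census <- function(census, path) {
  df <- data.frame(
    class_canon = names(census$joint_counts),
    k = census$k,
    joint_count = as.integer(census$joint_counts),
    disjoint_count = as.integer(census$disjoint_counts),
    joint_ratio = as.numeric(motif_frequencies(census, "JOINT_RATIO")),
    disjoint_ratio = as.numeric(motif_frequencies(census, "DISJOINT_RATIO")))
  write.csv(df, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(list(k = census$k, overlap_policy = census$overlap_policy,
                            mis_seed = census$mis_seed,
                            total_joint = census$total_joint,
                            total_disjoint = census$total_disjoint),
                       side, auto_unbox = TRUE)
  invisible(path)
}
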