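#' Read an undirected simple graph from a whitespace-separated edge list
#'
#' Each non-comment line names one edge by its two endpoint identifiers.
#' Identifiers are kept verbatim as strings (integer-looking labels are not
#' reinterpreted). Self-loops are dropped with a warning and duplicate edges
#' (in either orientation) are collapsed, so the result is always a simple
#' undirected graph.
#'
#' @param path path to the edge-list file
#' @param comment_prefix lines starting with this character are skipped
#' @return an undirected simple [igraph::graph] with character vertex names
#' @export
load_edge_list <- function(path, comment_prefix = "#") {
  if (!file.exists(path)) stop("cannot read edge list: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), comment_prefix) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) stop("edge list is empty: ", path)
  toks <- strsplit(trimws(lines[idx]), "[[:space:]]+")
  bad <- which(lengths(toks) < 2)
  if (length(bad) > 0) {
    stop("parse error in ", path, ": line ", idx[bad[1]],
         " has fewer than 2 tokens")
  }
  from <- vapply(toks, `[`, "", 1)
  to <- vapply(toks, `[`, "", 2)
  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped while reading ", path)
    from <- from[!loops]; to <- to[!loops]
  }
  if (length(from) == 0) stop("edge list contains only self-loops: ", path)
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to,
                                                stringsAsFactors = FALSE),
                                     directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a graph as a whitespace-separated edge list
#'
#' Inverse of [load_edge_list()]: one `u v` pair per line, vertex names
#' verbatim. Isolated vertices cannot be represented and are skipped.
#'
#' @param g an undirected igraph with vertex names
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Global topological statistics of a graph
#'
#' The summary used to characterize corpora: node and edge counts, density,
#' global (transitivity-based) clustering, and degree assortativity. The
#' global clustering coefficient is 3 x (number of triangles) / (number of
#' connected node triples), reported as 0 for graphs without any connected
#' triple. Degree assortativity is the Pearson correlation of degrees over
#' the 2m ordered edge-endpoint pairs and is `NaN` when the endpoint degree
#' sequence has zero variance (e.g. regular graphs).
#'
#' @param g an undirected simple graph with at least 2 nodes
#' @return a list of class `graph_stats` with fields `n_nodes`, `n_edges`,
#'   `density`, `global_clustering`, `degree_assortativity`
#' @export
compute_stats <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop("compute_stats needs at least 2 nodes")
  cl <- igraph::transitivity(g, type = "global")
  if (is.nan(cl)) cl <- 0
  structure(list(
    n_nodes = n,
    n_edges = igraph::ecount(g),
    density = 2 * igraph::ecount(g) / (n * (n - 1)),
    global_clustering = cl,
    degree_assortativity = suppressWarnings(igraph::assortativity_degree(g))
  ), class = "graph_stats")
}

#' @export
print.graph_stats <- function(x, ...) {
  cat(sprintf(
    "graph: %d nodes, %d edges | density %.4g | clustering %.4g | assortativity %.4g\n",
    x$n_nodes, x$n_edges, x$density, x$global_clustering,
    x$degree_assortativity))
  invisible(x)
}

#' Induced subgraph on a node subset
#'
#' Returns the graph on exactly `nodes` with every host edge whose two
#' endpoints both lie in the subset.
#'
#' @param g host graph
#' @param nodes character vector of vertex names (non-empty, all present in `g`)
#' @return the induced subgraph
#' @export
induced_on <- function(g, nodes) {
  if (length(nodes) == 0) stop("node subset must be non-empty")
  known <- nodes %in% igraph::V(g)$name
  if (!all(known)) {
    stop("unknown node(s) in subset: ", paste(nodes[!known][1:min(3, sum(!known))],
                                              collapse = ", "))
  }
  igraph::induced_subgraph(g, nodes)
}

#' Largest connected component
#'
#' Induced subgraph on the maximum-cardinality connected node set. Ties in
#' component size are broken deterministically in favour of the component
#' containing the lexicographically smallest vertex name.
#'
#' @param g an undirected graph with vertex names
#' @return the induced subgraph on the winning component
#' @export
largest_component <- function(g) {
  comp <- igraph::components(g)
  mx <- max(comp$csize)
  cand <- which(comp$csize == mx)
  if (length(cand) > 1) {
    # smallest lexicographic member decides
    firsts <- vapply(cand, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, "")
    cand <- cand[order(firsts)][1]
  }
  igraph::induced_subgraph(g, which(comp$membership == cand[1]))
}

# 1-based sorted adjacency list representation used by the C++ census and
# the R-level walkers.
adjacency_list_int <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), function(v) sort(as.integer(v)))
}
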