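#' Specify a synthetic interest-network topic
#'
#' A topic is modelled as a series of monthly graphs sharing target
#' topological statistics: node count, density, global clustering and
#' degree assortativity. Targets correspond to the averaged per-topic
#' statistics of real discussion networks.
#'
#' @param label topic name
#' @param n_nodes average node count
#' @param target_density edge density in [0, 1]
#' @param target_clustering global clustering coefficient in [0, 1]
#' @param target_assortativity degree assortativity in [-1, 1]
#' @param months number of monthly graphs (default 11)
#' @return list of class `topic_spec`
#' @export
topic_spec <- function(label, n_nodes, target_density, target_clustering,
                       target_assortativity, months = 11) {
  stopifnot(n_nodes >= 10, target_density > 0, target_density <= 1,
            target_clustering >= 0, target_clustering <= 1,
            target_assortativity >= -1, target_assortativity <= 1,
            months >= 1)
  m <- round(target_density * n_nodes * (n_nodes - 1) / 2)
  if (m < 1) stop("spec implies an empty graph")
  structure(list(label = label, n_nodes = as.integer(n_nodes),
                 target_density = target_density,
                 target_clustering = target_clustering,
                 target_assortativity = target_assortativity,
                 months = as.integer(months)),
            class = "topic_spec")
}

#' Bundled topic specifications
#'
#' The six topics used for the worked corpus (counterstrike, freedonuts,
#' feminism, introvert, pizza, stopsmoking), with their averaged node
#' counts, clustering, density and assortativity. The full 26-topic table
#' ships as `topics_table.tsv` in the package's `extdata`.
#'
#' @param labels optional subset of topic labels to return
#' @param months monthly graphs per topic
#' @return list of [topic_spec()] objects
#' @export
bundled_topic_specs <- function(labels = NULL, months = 11) {
  path <- system.file("extdata", "topics_table.tsv", package = "netblocks")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(labels)) {
    labels <- c("counterstrike", "freedonuts", "feminism", "introvert",
                "pizza", "stopsmoking")
  }
  miss <- setdiff(labels, tab$label)
  if (length(miss) > 0)
    stop("unknown topic label(s): ", paste(miss, collapse = ", "))
  lapply(labels, function(lb) {
    row <- tab[tab$label == lb, ]
    topic_spec(lb, n_nodes = round(row$nodes),
               target_density = row$density,
               target_clustering = row$clustering,
               target_assortativity = row$assortativity,
               months = months)
  })
}

#' Generate one synthetic topic graph
#'
#' Three-phase construction, each phase controlling one target statistic
#' while approximately preserving the earlier ones:
#' \enumerate{
#'   \item a degree-heterogeneous random graph with exactly the implied
#'     edge count, edge probability proportional to the product of
#'     power-law-like node weights (exponent 2.5);
#'   \item triangle rewiring: wedge-closing (or triangle-breaking, when the
#'     start is above target) moves accepted while they bring the global
#'     clustering closer to target, up to `20 m` attempts;
#'   \item degree-preserving two-edge swaps accepted when they move the
#'     degree assortativity toward target without pushing clustering out of
#'     tolerance, up to `20 m` attempts.
#' }
#' The whole (possibly disconnected) graph is returned with exact density;
#' callers needing connectivity take [largest_component()].
#'
#' Achieved statistics must fall within tolerance (density 20% relative -
#' exact here by construction; clustering within the larger of 0.01 and 50%
#' relative; assortativity within 0.07), otherwise generation fails with
#' the achieved statistics in the error.
#'
#' @param spec a [topic_spec()]
#' @param seed integer seed; identical seeds give byte-identical edge lists
#' @param n_override node count replacing `spec$n_nodes` (used for the
#'   monthly jitter)
#' @return an undirected simple igraph with character vertex names and a
#'   `graph_stats` attribute `achieved_stats`
#' @export
generate_topic_graph <- function(spec, seed = 1L, n_override = NULL) {
  stopifnot(inherits(spec, "topic_spec"))
  set.seed(seed)
  n <- as.integer(n_override %||% spec$n_nodes)
  m <- round(spec$target_density * n * (n - 1) / 2)
  m <- min(m, n * (n - 1) / 2)
  if (m < 1) stop("generation error: spec implies an empty graph")

  # phase 1: fixed edge count, power-law-like expected degrees. The weight
  # exponent starts at the value implied by a degree exponent of 2.5 and is
  # steepened only if the realized degree sequence cannot support the
  # assortativity target (checked against the sorted stub-pairing bound).
  expo <- -1 / (2.5 - 1)
  for (try in 1:4) {
    g <- igraph::sample_fitness(m, fitness.out = seq_len(n)^expo)
    lb <- assortativity_lower_bound(igraph::degree(g))
    if (is.nan(lb) || lb <= spec$target_assortativity + 0.03 ||
        spec$target_assortativity > 0) break
    expo <- expo * 1.3
  }
  st <- graph_state(g)

  # phase 2: clustering toward target
  st <- phase_clustering(st, spec$target_clustering, max_attempts = 20 * m)

  # phase 3: assortativity toward target, clustering kept in tolerance
  cl_tol <- max(0.01, 0.5 * spec$target_clustering)
  st <- phase_assortativity(st, spec$target_assortativity,
                            spec$target_clustering, cl_tol,
                            max_attempts = 20 * m)

  g <- igraph::graph_from_edgelist(state_edges(st), directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- as.character(seq_len(n))
  ach <- compute_stats(g)
  check_tolerances(ach, spec, cl_tol)
  attr(g, "achieved_stats") <- ach
  g
}

check_tolerances <- function(ach, spec, cl_tol) {
  ok_d <- abs(ach$density - spec$target_density) <= 0.2 * spec$target_density
  ok_c <- abs(ach$global_clustering - spec$target_clustering) <= cl_tol
  a <- ach$degree_assortativity
  # NaN assortativity means zero endpoint-degree variance (regular graph):
  # no degree-preserving rewiring can move it, so the check is vacuous
  ok_a <- is.nan(a) || abs(a - spec$target_assortativity) <= 0.07
  if (!(ok_d && ok_c && ok_a)) {
    stop(sprintf(
      "generation error for '%s': achieved density %.5f / clustering %.4f / assortativity %.4f vs targets %.5f / %.4f / %.4f",
      spec$label, ach$density, ach$global_clustering, a,
      spec$target_density, spec$target_clustering,
      spec$target_assortativity))
  }
  invisible(TRUE)
}

# --- incremental rewiring machinery ----------------------------------------
# State: adjacency sets (integer vectors), degrees, edge matrix, triangle
# count T, connected-triple count P = sum C(d,2), and the endpoint-degree
# sums needed for incremental assortativity.

graph_state <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- igraph::vcount(g)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  for (e in seq_len(nrow(el))) {
    u <- el[e, 1]; v <- el[e, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  deg <- lengths(adj)
  Tcount <- sum(vapply(seq_len(nrow(el)), function(e)
    length(intersect(adj[[el[e, 1]]], adj[[el[e, 2]]])), 0L)) / 3
  list(adj = adj, deg = deg, edges = el, n = n,
       T = Tcount, P = sum(choose(deg, 2)))
}

state_edges <- function(st) st$edges

state_clustering <- function(st) if (st$P == 0) 0 else 3 * st$T / st$P

common_nb <- function(st, u, v) length(intersect(st$adj[[u]], st$adj[[v]]))

st_has_edge <- function(st, u, v) v %in% st$adj[[u]]

st_add_edge <- function(st, u, v) {
  st$T <- st$T + common_nb(st, u, v)
  st$P <- st$P + st$deg[u] + st$deg[v]
  st$adj[[u]] <- c(st$adj[[u]], v)
  st$adj[[v]] <- c(st$adj[[v]], u)
  st$deg[u] <- st$deg[u] + 1L
  st$deg[v] <- st$deg[v] + 1L
  st$edges <- rbind(st$edges, c(u, v))
  st
}

st_remove_edge <- function(st, eidx) {
  u <- st$edges[eidx, 1]; v <- st$edges[eidx, 2]
  st$adj[[u]] <- st$adj[[u]][st$adj[[u]] != v]
  st$adj[[v]] <- st$adj[[v]][st$adj[[v]] != u]
  st$deg[u] <- st$deg[u] - 1L
  st$deg[v] <- st$deg[v] - 1L
  st$T <- st$T - common_nb(st, u, v)
  st$P <- st$P - st$deg[u] - st$deg[v]
  st$edges <- st$edges[-eidx, , drop = FALSE]
  st
}

# Stub-pairing relaxation bound: the most negative Pearson degree
# assortativity any simple wiring of this degree sequence could plausibly
# reach (pairs the largest stubs with the smallest).
assortativity_lower_bound <- function(deg) {
  deg <- deg[deg > 0]
  m <- sum(deg) / 2
  if (m < 2) return(NaN)
  stubs <- sort(rep(deg, deg))
  Se_min <- sum(stubs * rev(stubs)) / 2
  mu <- sum(deg^2) / (2 * m)
  var_ <- sum(deg^3) / (2 * m) - mu^2
  if (var_ <= 0) return(NaN)
  (Se_min / m - mu^2) / var_
}

# Wedge-closing / triangle-breaking rewiring with constant edge count. The
# paying edge for a wedge closure is chosen among a few random candidates,
# preferring one that sits in no triangle so the closure's gain is not
# cancelled.
phase_clustering <- function(st, target, max_attempts) {
  for (att in seq_len(max_attempts)) {
    cur <- state_clustering(st)
    if (abs(cur - target) <= 1e-4) break
    if (cur < target) {
      cands <- which(st$deg >= 2)
      if (length(cands) == 0) break
      v <- cands[sample.int(length(cands), 1)]
      nb <- st$adj[[v]]
      uw <- nb[sample.int(length(nb), 2)]
      if (st_has_edge(st, uw[1], uw[2])) next
      eidx <- 0L
      for (cand in sample.int(nrow(st$edges), min(5, nrow(st$edges)))) {
        ex <- st$edges[cand, ]
        if (any(ex %in% c(uw, v))) next
        eidx <- cand
        if (common_nb(st, ex[1], ex[2]) == 0) break # triangle-free payer
      }
      if (eidx == 0L) next
      st2 <- st_remove_edge(st, eidx)
      st2 <- st_add_edge(st2, uw[1], uw[2])
      if (abs(state_clustering(st2) - target) < abs(cur - target)) st <- st2
    } else {
      # break a random edge, reconnect two random non-adjacent nodes
      eidx <- sample.int(nrow(st$edges), 1)
      uv <- sample.int(st$n, 2)
      if (st_has_edge(st, uv[1], uv[2])) next
      if (any(st$edges[eidx, ] %in% uv)) next
      st2 <- st_remove_edge(st, eidx)
      st2 <- st_add_edge(st2, uv[1], uv[2])
      if (abs(state_clustering(st2) - target) < abs(cur - target)) st <- st2
    }
  }
  st
}

state_assortativity <- function(st) {
  d <- st$deg
  m <- nrow(st$edges)
  du <- d[st$edges[, 1]]; dv <- d[st$edges[, 2]]
  mu <- sum(du + dv) / (2 * m)
  var_ <- sum(du^2 + dv^2) / (2 * m) - mu^2
  if (var_ <= 0) return(NaN)
  (sum(du * dv) / m - mu^2) / var_
}

# Degree-preserving two-edge swaps toward a target assortativity. Degrees
# are invariant, so only the endpoint degree product sum changes; clustering
# is kept within tolerance of its target. Proposals are targeted: when the
# assortativity must decrease, the first edge is drawn with probability
# proportional to its endpoint degree product (the assortative edges that
# need breaking); both valid re-pairings of the chosen edge pair are
# evaluated and the better one applied when it strictly improves.
phase_assortativity <- function(st, target, cl_target, cl_tol, max_attempts) {
  d <- st$deg
  m <- nrow(st$edges)
  mu <- sum(d^2) / (2 * m)
  var_ <- sum(d^3) / (2 * m) - mu^2
  if (var_ <= 0) return(st)
  Se <- sum(d[st$edges[, 1]] * d[st$edges[, 2]])
  r_of <- function(Se) (Se / m - mu^2) / var_
  prods <- d[st$edges[, 1]] * d[st$edges[, 2]]
  for (att in seq_len(max_attempts)) {
    gap <- r_of(Se) - target
    if (abs(gap) <= 0.005) break
    wts <- if (gap > 0) prods else 1 / prods
    e_a <- sample.int(m, 1, prob = wts)
    e_b <- sample.int(m, 1)
    if (e_a == e_b) next
    e1 <- st$edges[e_a, ]; e2 <- st$edges[e_b, ]
    if (length(unique(c(e1, e2))) < 4) next
    pairings <- list(list(p1 = c(e1[1], e2[1]), p2 = c(e1[2], e2[2])),
                     list(p1 = c(e1[1], e2[2]), p2 = c(e1[2], e2[1])))
    best <- NULL
    best_gap <- abs(gap)
    best_dSe <- 0
    for (o in pairings) {
      if (st_has_edge(st, o$p1[1], o$p1[2]) ||
          st_has_edge(st, o$p2[1], o$p2[2])) next
      dSe <- d[o$p1[1]] * d[o$p1[2]] + d[o$p2[1]] * d[o$p2[2]] -
        prods[e_a] - prods[e_b]
      ng <- abs(r_of(Se + dSe) - target)
      if (ng < best_gap) { best <- o; best_gap <- ng; best_dSe <- dSe }
    }
    if (is.null(best)) next
    st2 <- st_remove_edge(st, max(e_a, e_b))
    st2 <- st_remove_edge(st2, min(e_a, e_b))
    st2 <- st_add_edge(st2, best$p1[1], best$p1[2])
    st2 <- st_add_edge(st2, best$p2[1], best$p2[2])
    if (abs(state_clustering(st2) - cl_target) > cl_tol) next
    st <- st2
    Se <- Se + best_dSe
    # the two new edges sit at the end of the edge matrix
    prods <- prods[-c(e_a, e_b)]
    prods <- c(prods, d[best$p1[1]] * d[best$p1[2]],
               d[best$p2[1]] * d[best$p2[2]])
  }
  st
}

#' Generate a corpus of monthly topic graphs
#'
#' For every topic, `months` graphs are generated with per-month seeds
#' derived from `base_seed` and the topic label, the monthly node count
#' jittered by +/-10% around the topic's average. Failures (targets not
#' reached within the rewiring budget) are recorded in the manifest and do
#' not abort the corpus.
#'
#' @param specs list of [topic_spec()] objects
#' @param base_seed master seed for the corpus
#' @return list of class `corpus`: `graphs` (named list,
#'   `<label>_m<month>`), `manifest` (data.frame with per-graph seed,
#'   achieved stats and failure flag)
#' @export
generate_corpus <- function(specs, base_seed = 1L) {
  if (inherits(specs, "topic_spec")) specs <- list(specs)
  graphs <- list()
  rows <- list()
  for (spec in specs) {
    for (mo in seq_len(spec$months)) {
      sd <- derive_seed(base_seed, spec$label, mo)
      set.seed(sd)
      n_mo <- max(10L, as.integer(round(spec$n_nodes * runif(1, 0.9, 1.1))))
      id <- sprintf("%s_m%02d", spec$label, mo)
      res <- tryCatch(generate_topic_graph(spec, seed = sd, n_override = n_mo),
                      error = function(e) e)
      failed <- inherits(res, "error")
      if (!failed) graphs[[id]] <- res
      ach <- if (failed) NULL else attr(res, "achieved_stats")
      rows[[id]] <- data.frame(
        graph_id = id, label = spec$label, month = mo, seed = sd,
        n_nodes = if (failed) NA else ach$n_nodes,
        n_edges = if (failed) NA else ach$n_edges,
        density = if (failed) NA else ach$density,
        clustering = if (failed) NA else ach$global_clustering,
        assortativity = if (failed) NA else ach$degree_assortativity,
        failed = failed,
        message = if (failed) conditionMessage(res) else "",
        stringsAsFactors = FALSE)
    }
  }
  structure(list(graphs = graphs, manifest = do.call(rbind, rows)),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("corpus: %d graphs (%d failed) over %d topics\n",
              nrow(x$manifest), sum(x$manifest$failed),
              length(unique(x$manifest$label))))
  invisible(x)
}

#' Deterministic toy fixture graphs
#'
#' Small named graphs used across the test-suite and examples: `triangle`,
#' `path10`, `star10` (hub plus 9 leaves), `cycle6`, `K4`, `K10`,
#' `two_triangles_shared_node` (bowtie), `barbell_5_5` (two K5 joined by
#' one edge).
#'
#' @return named list of undirected igraphs with character vertex names
#' @export
fixture_graphs <- function() {
  named <- function(g) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    g
  }
  barbell <- igraph::disjoint_union(igraph::make_full_graph(5),
                                    igraph::make_full_graph(5))
  barbell <- igraph::add_edges(barbell, c(5, 6))
  bowtie <- igraph::graph_from_edgelist(
    cbind(c(1, 2, 1, 3, 3, 4), c(2, 5, 5, 4, 5, 5)), directed = FALSE)
  list(
    triangle = named(igraph::make_full_graph(3)),
    path10 = named(igraph::make_lattice(10)),
    star10 = named(igraph::make_star(10, mode = "undirected")),
    cycle6 = named(igraph::make_ring(6)),
    K4 = named(igraph::make_full_graph(4)),
    K10 = named(igraph::make_full_graph(10)),
    two_triangles_shared_node = named(bowtie),
    barbell_5_5 = named(barbell))
}
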