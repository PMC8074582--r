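#' Sampler methods implemented by the package
#'
#' Node-based: `RN` (uniform random nodes), `DEGREE` (degree-proportional
#' nodes), `PRN` (PageRank-proportional nodes). Edge-based: `RE` (uniform
#' random edges). Exploration-based: `SB` (snowball / capped BFS), `CSE`
#' (community structure expansion), `SP` (shortest-path accumulation).
#' Walk-based: `RW` (simple random walk), `MHRW` (Metropolis-Hastings walk,
#' uniform stationary distribution), `RWJ` (random walk with jumps), `NBRW`
#' (non-backtracking random walk).
#'
#' @export
SAMPLER_METHODS <- c("RN", "DEGREE", "PRN", "RE", "SB", "CSE", "SP",
                     "RW", "MHRW", "RWJ", "NBRW")

#' Specify a sampling request
#'
#' @param method one of [SAMPLER_METHODS] (case-insensitive)
#' @param target_size number of nodes to sample (>= 2)
#' @param rng_seed integer seed; identical `(graph, spec)` pairs give
#'   identical samples
#' @param params method-specific parameters: `k` snowball branching
#'   (default 10), `p` jump probability for RWJ (default 0.1), `d` PageRank
#'   damping for PRN (default 0.85), `keep_trace` to retain the walk trace
#' @return a list of class `sampler_spec`
#' @export
sampler_spec <- function(method, target_size, rng_seed = 1L, params = list()) {
  method <- toupper(method)
  if (!method %in% SAMPLER_METHODS)
    stop("unknown sampling method: ", method)
  if (target_size < 2) stop("target_size must be >= 2")
  p <- params$p %||% 0.1
  k <- params$k %||% 10L
  d <- params$d %||% 0.85
  if (p <= 0 || p >= 1) stop("jump probability p must be in (0,1)")
  if (k < 1) stop("snowball branching k must be >= 1")
  if (d <= 0 || d >= 1) stop("PageRank damping d must be in (0,1)")
  params$p <- p; params$k <- as.integer(k); params$d <- d
  structure(list(method = method, target_size = as.integer(target_size),
                 params = params, rng_seed = as.integer(rng_seed)),
            class = "sampler_spec")
}

#' Draw one sample of a host graph
#'
#' Dispatches on `spec$method`. The host is expected to be connected
#' (callers typically pass [largest_component()]). All methods except `RE`
#' return the subgraph induced on exactly `target_size` nodes; `RE` returns
#' the edge-sampled (non-induced) subgraph whose node count is
#' `target_size` or `target_size + 1`.
#'
#' @param g connected undirected host graph with vertex names
#' @param spec a [sampler_spec()]
#' @param host_id optional host label carried into the result
#' @return a list of class `sample_result` with fields `subgraph`, `spec`,
#'   `actual_size`, `host_id` and (for walk methods with `keep_trace`)
#'   `trace`
#' @export
draw_sample <- function(g, spec, host_id = NA_character_) {
  stopifnot(inherits(spec, "sampler_spec"))
  n <- spec$target_size
  if (n > igraph::vcount(g))
    stop("target_size ", n, " exceeds host size ", igraph::vcount(g))
  set.seed(spec$rng_seed)
  res <- switch(spec$method,
    RN = , DEGREE = , PRN = sample_node_based(g, spec),
    RE = sample_random_edge(g, spec),
    SB = , CSE = , SP = sample_exploration(g, spec),
    RW = , MHRW = , RWJ = , NBRW = sample_walk(g, spec))
  res$spec <- spec
  res$host_id <- host_id
  res$actual_size <- igraph::vcount(res$subgraph)
  class(res) <- "sample_result"
  res
}

#' @export
print.sample_result <- function(x, ...) {
  cat(sprintf("sample_result: %s, %d nodes, %d edges (host %s, seed %d)\n",
              x$spec$method, x$actual_size, igraph::ecount(x$subgraph),
              x$host_id, x$spec$rng_seed))
  invisible(x)
}

# --- node-based -------------------------------------------------------------

sample_node_based <- function(g, spec) {
  n <- spec$target_size
  nv <- igraph::vcount(g)
  w <- switch(spec$method,
    RN = NULL,
    DEGREE = igraph::degree(g),
    PRN = igraph::page_rank(g, damping = spec$params$d)$vector)
  idx <- if (is.null(w)) sample.int(nv, n) else sample.int(nv, n, prob = w)
  list(subgraph = igraph::induced_subgraph(g, idx))
}

# --- edge-based -------------------------------------------------------------

sample_random_edge <- function(g, spec) {
  n <- spec$target_size
  el <- igraph::as_edgelist(g, names = FALSE)
  ord <- sample.int(nrow(el))
  seen <- integer(0)
  take <- 0L
  for (i in ord) {
    take <- take + 1L
    seen <- union(seen, el[i, ])
    if (length(seen) >= n) break
  }
  sg <- igraph::subgraph_from_edges(g, ord[seq_len(take)],
                                    delete.vertices = TRUE)
  list(subgraph = sg)
}

# --- exploration-based ------------------------------------------------------

sample_exploration <- function(g, spec) {
  adj <- adjacency_list_int(g)
  idx <- switch(spec$method,
    SB = explore_snowball(adj, spec$target_size, spec$params$k),
    CSE = explore_cse(adj, spec$target_size),
    SP = explore_shortest_paths(adj, spec$target_size))
  list(subgraph = igraph::induced_subgraph(g, idx))
}

# Snowball: BFS keeping at most k uniformly chosen unvisited neighbours per
# expanded node. If the capped frontier empties before n nodes are
# collected, BFS restarts from a fresh uniform unvisited node, keeping what
# was already collected.
explore_snowball <- function(adj, n, k) {
  nv <- length(adj)
  visited <- logical(nv)
  collected <- integer(0)
  queue <- integer(0)
  repeat {
    if (length(collected) >= n) break
    if (length(queue) == 0) {
      unvis <- which(!visited)
      seed <- unvis[sample.int(length(unvis), 1)]
      visited[seed] <- TRUE
      collected <- c(collected, seed)
      if (length(collected) >= n) break
      queue <- seed
      next
    }
    u <- queue[1]; queue <- queue[-1]
    nb <- adj[[u]][!visited[adj[[u]]]]
    if (length(nb) > k) nb <- sample(nb, k)
    else if (length(nb) > 1) nb <- sample(nb)
    for (v in nb) {
      visited[v] <- TRUE
      collected <- c(collected, v)
      queue <- c(queue, v)
      if (length(collected) >= n) break
    }
  }
  collected[seq_len(n)]
}

# Community structure expansion: repeatedly add the boundary node that can
# reach the most nodes outside the current set and its boundary.
explore_cse <- function(adj, n) {
  nv <- length(adj)
  in_set <- logical(nv)
  start <- sample.int(nv, 1)
  in_set[start] <- TRUE
  set <- start
  while (length(set) < n) {
    boundary <- setdiff(unique(unlist(adj[set])), set)
    if (length(boundary) == 0) { # exhausted component (disconnected host)
      rest <- which(!in_set)
      pick <- if (length(rest) > 1) sample(rest, 1) else rest
      in_set[pick] <- TRUE; set <- c(set, pick)
      next
    }
    known <- c(set, boundary)
    gain <- vapply(boundary, function(b) sum(!(adj[[b]] %in% known)), 0L)
    best <- boundary[gain == max(gain)]
    pick <- if (length(best) > 1) sample(best, 1) else best
    in_set[pick] <- TRUE
    set <- c(set, pick)
  }
  set
}

# One shortest path between u and v via BFS with uniformly shuffled
# neighbour order (random tie-breaking among equally short paths).
random_shortest_path <- function(adj, u, v) {
  nv <- length(adj)
  parent <- integer(nv)
  seenb <- logical(nv)
  seenb[u] <- TRUE
  queue <- u
  while (length(queue) > 0 && !seenb[v]) {
    x <- queue[1]; queue <- queue[-1]
    nb <- adj[[x]][!seenb[adj[[x]]]]
    if (length(nb) > 1) nb <- sample(nb)
    for (y in nb) {
      seenb[y] <- TRUE; parent[y] <- x; queue <- c(queue, y)
      if (y == v) break
    }
  }
  if (!seenb[v]) return(NULL)
  path <- v
  while (path[1] != u) path <- c(parent[path[1]], path)
  path
}

# Shortest-path sampling: accumulate nodes of random shortest paths; the
# first pair is uniform, later paths start from an already-collected node
# (keeping the sample connected) and end at a uniform outside node. The
# final path is truncated from its far end so the sample lands exactly on
# n nodes.
explore_shortest_paths <- function(adj, n) {
  nv <- length(adj)
  collected <- integer(0)
  guard <- 0L
  while (length(collected) < n) {
    guard <- guard + 1L
    if (guard > 100L * nv) stop("shortest-path sampling stalled")
    if (length(collected) == 0) {
      uv <- sample.int(nv, 2)
    } else {
      u <- collected[sample.int(length(collected), 1)]
      rest <- setdiff(seq_len(nv), collected)
      v <- rest[sample.int(length(rest), 1)]
      uv <- c(u, v)
    }
    path <- random_shortest_path(adj, uv[1], uv[2])
    if (is.null(path)) next
    new_nodes <- setdiff(path, collected)
    if (length(collected) + length(new_nodes) > n) {
      # drop surplus new nodes from the far (v) end of the path
      surplus <- length(collected) + length(new_nodes) - n
      drop <- intersect(rev(path), new_nodes)[seq_len(surplus)]
      new_nodes <- setdiff(new_nodes, drop)
    }
    collected <- c(collected, new_nodes)
  }
  collected
}

# --- walk-based -------------------------------------------------------------

sample_walk <- function(g, spec) {
  adj <- adjacency_list_int(g)
  nv <- length(adj)
  n <- spec$target_size
  method <- spec$method
  p_jump <- spec$params$p
  keep_trace <- isTRUE(spec$params$keep_trace)
  deg <- lengths(adj)

  stall_limit <- 1000 * nv
  restarts <- 0L
  visited <- logical(nv)
  collected <- integer(0)
  trace <- integer(0)

  cur <- sample.int(nv, 1)
  prev <- NA_integer_
  visited[cur] <- TRUE
  collected <- cur
  if (keep_trace) trace <- cur
  since_new <- 0L

  while (length(collected) < n) {
    nxt <- switch(method,
      RW = {
        nb <- adj[[cur]]
        if (length(nb) == 1) nb else nb[sample.int(length(nb), 1)]
      },
      MHRW = {
        nb <- adj[[cur]]
        v <- if (length(nb) == 1) nb else nb[sample.int(length(nb), 1)]
        if (runif(1) < min(1, deg[cur] / deg[v])) v else cur
      },
      RWJ = {
        if (runif(1) < p_jump) {
          prev <- NA_integer_
          sample.int(nv, 1)
        } else {
          nb <- adj[[cur]]
          if (length(nb) == 1) nb else nb[sample.int(length(nb), 1)]
        }
      },
      NBRW = {
        nb <- adj[[cur]]
        if (length(nb) > 1 && !is.na(prev)) nb <- nb[nb != prev]
        if (length(nb) == 1) nb else nb[sample.int(length(nb), 1)]
      })
    if (method != "MHRW" || nxt != cur) prev <- cur
    cur <- nxt
    if (keep_trace) trace <- c(trace, cur)
    if (!visited[cur]) {
      visited[cur] <- TRUE
      collected <- c(collected, cur)
      since_new <- 0L
    } else {
      since_new <- since_new + 1L
      if (since_new >= stall_limit) {
        restarts <- restarts + 1L
        if (restarts > 10L)
          stop("sampling error: ", method,
               " walk exhausted its restart budget")
        cur <- sample.int(nv, 1)
        prev <- NA_integer_
        since_new <- 0L
        if (keep_trace) trace <- c(trace, NA_integer_, cur)
        if (!visited[cur]) { visited[cur] <- TRUE; collected <- c(collected, cur) }
      }
    }
  }
  out <- list(subgraph = igraph::induced_subgraph(g, collected))
  if (keep_trace) out$trace <- igraph::V(g)$name[trace]
  out
}

#' Long-run node visit frequencies of a walk chain
#'
#' Runs a walk of `n_steps` steps (counting stays for MHRW) and returns the
#' per-node visit frequencies. Used to check the stationary distribution:
#' uniform for `MHRW`, degree-proportional for `RW`.
#'
#' @param g connected undirected graph
#' @param method `"RW"` or `"MHRW"`
#' @param n_steps chain length
#' @param rng_seed integer seed
#' @return named numeric vector of visit frequencies summing to 1
#' @export
walk_visit_frequencies <- function(g, method = c("RW", "MHRW"),
                                   n_steps = 1e5, rng_seed = 1L) {
  method <- match.arg(method)
  adj <- adjacency_list_int(g)
  deg <- lengths(adj)
  nv <- length(adj)
  set.seed(rng_seed)
  counts <- integer(nv)
  cur <- sample.int(nv, 1)
  for (i in seq_len(n_steps)) {
    nb <- adj[[cur]]
    v <- if (length(nb) == 1) nb else nb[sample.int(length(nb), 1)]
    if (method == "MHRW" && runif(1) >= min(1, deg[cur] / deg[v])) v <- cur
    cur <- v
    counts[cur] <- counts[cur] + 1L
  }
  setNames(counts / n_steps, igraph::V(g)$name)
}
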