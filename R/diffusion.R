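#' SI simulation parameters
#'
#' @param r per-edge per-step infection probability in (0, 1]
#' @param seed_policy `"UNIFORM_NODE"` (one uniformly chosen initially
#'   infected node per run) or `"FIXED_NODE"` with `seed_node`
#' @param seed_node vertex name of the fixed initial infected node
#' @param theta activation fraction in (0, 1]; `theta = 1` means full
#'   activation of the seed's component
#' @param max_steps cap on simulated steps; runs that do not reach the
#'   target within the cap are censored
#' @return list of class `si_params`
#' @export
si_params <- function(r = 0.3, seed_policy = c("UNIFORM_NODE", "FIXED_NODE"),
                      seed_node = NULL, theta = 1.0, max_steps = 1e4) {
  seed_policy <- match.arg(seed_policy)
  if (r <= 0 || r > 1) stop("infection rate r must be in (0, 1]")
  if (theta <= 0 || theta > 1) stop("activation fraction theta must be in (0, 1]")
  if (seed_policy == "FIXED_NODE" && is.null(seed_node))
    stop("FIXED_NODE seed policy needs seed_node")
  structure(list(r = r, seed_policy = seed_policy, seed_node = seed_node,
                 theta = theta, max_steps = as.integer(max_steps)),
            class = "si_params")
}

#' Simulate one discrete-time SI epidemic run
#'
#' Synchronous (generation-based) updates: at every step each susceptible
#' node with m currently infected neighbours becomes infected with
#' probability 1 - (1-r)^m (independent per-neighbour Bernoulli exposures).
#' The run starts from a single infected node and stops when the infected
#' count reaches `theta` times the number of nodes reachable from the seed,
#' or at `max_steps` (censored).
#'
#' @param g undirected graph (callers usually pass [largest_component()])
#' @param params an [si_params()] object
#' @param run_seed integer seed; identical seeds reproduce identical traces
#' @return list of class `diffusion_trace`: `infected_counts` (I_0, I_1,
#'   ...), `tau` (step index, or `NA` when censored), `censored`,
#'   `seed_node`, `run_seed`, `n_reachable`
#' @export
simulate_si <- function(g, params = si_params(), run_seed = 1L) {
  stopifnot(inherits(params, "si_params"))
  set.seed(run_seed)
  nv <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  seed_idx <- if (params$seed_policy == "FIXED_NODE") {
    i <- match(params$seed_node, nm)
    if (is.na(i)) stop("seed_node not in graph: ", params$seed_node)
    i
  } else sample.int(nv, 1)
  reach <- as.integer(igraph::subcomponent(g, seed_idx, mode = "all"))
  n_reach <- length(reach)
  target <- ceiling(params$theta * n_reach)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  infected <- logical(nv)
  infected[seed_idx] <- TRUE
  counts <- integer(0)
  counts[1] <- 1L
  t <- 0L
  while (sum(infected) < target && t < params$max_steps) {
    m <- as.vector(A %*% infected)
    sus <- !infected & m > 0
    p <- 1 - (1 - params$r)^m[sus]
    newly <- which(sus)[runif(sum(sus)) < p]
    infected[newly] <- TRUE
    t <- t + 1L
    counts[t + 1L] <- sum(infected)
  }
  censored <- sum(infected) < target
  structure(list(infected_counts = counts,
                 tau = if (censored) NA_integer_ else t,
                 censored = censored,
                 seed_node = nm[seed_idx], run_seed = as.integer(run_seed),
                 n_reachable = n_reach),
            class = "diffusion_trace")
}

#' @export
print.diffusion_trace <- function(x, ...) {
  cat(sprintf("diffusion_trace: seed %s, tau %s (%d reachable, %d steps recorded)\n",
              x$seed_node, if (x$censored) "CENSORED" else x$tau,
              x$n_reachable, length(x$infected_counts) - 1L))
  invisible(x)
}

#' Estimate the SI transient time over repeated runs
#'
#' Runs [simulate_si()] with seeds `base_seed + 0 ... base_seed +
#' n_runs - 1` and summarizes tau over the uncensored runs.
#'
#' @param g undirected graph
#' @param params [si_params()]
#' @param n_runs number of runs (default 10)
#' @param base_seed first run seed
#' @return list of class `transient_estimate`: `mean_tau`, `sd_tau` (0 when
#'   a single uncensored run), `n_runs`, `n_censored`, `traces`
#' @export
estimate_transient_time <- function(g, params = si_params(), n_runs = 10,
                                    base_seed = 1L) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  traces <- lapply(seq_len(n_runs) - 1L,
                   function(i) simulate_si(g, params, base_seed + i))
  taus <- vapply(traces, function(tr) as.numeric(tr$tau), 0)
  ok <- !is.na(taus)
  if (!any(ok))
    stop("all ", n_runs, " SI runs were censored; increase max_steps or r")
  structure(list(mean_tau = mean(taus[ok]),
                 sd_tau = if (sum(ok) > 1) sd(taus[ok]) else 0,
                 n_runs = as.integer(n_runs),
                 n_censored = sum(!ok),
                 traces = traces),
            class = "transient_estimate")
}

#' @export
print.transient_estimate <- function(x, ...) {
  cat(sprintf("transient_estimate: mean tau %.3f (sd %.3f) over %d runs, %d censored\n",
              x$mean_tau, x$sd_tau, x$n_runs, x$n_censored))
  invisible(x)
}

#' Logistic mean-field reference for SI growth
#'
#' Closed-form solution of dI/dt = C r I (N - I):
#' I(t) = N I0 / (I0 + (N - I0) exp(-C r N t)), together with the
#' continuous transient time to reach theta*N,
#' tau = ln(theta (N - I0) / ((1 - theta) I0)) / (C r N). For theta = 1 the
#' transient time is infinite (the logistic only reaches N asymptotically)
#' and `Inf` is returned with a message.
#'
#' @param N population (node count)
#' @param C conductance prefactor (> 0)
#' @param r infection rate (> 0)
#' @param I0 initial infected count, 0 < I0 < theta*N
#' @param theta activation fraction in (0, 1]
#' @return list with `I` (vectorized function of t) and `tau_continuous`
#' @export
logistic_reference <- function(N, C, r, I0 = 1, theta = 1.0) {
  if (C <= 0 || r <= 0) stop("C and r must be positive")
  if (I0 <= 0 || I0 > theta * N) stop("need 0 < I0 <= theta*N")
  I <- function(t) N * I0 / (I0 + (N - I0) * exp(-C * r * N * t))
  tau <- if (theta >= 1) {
    message("theta = 1: logistic transient time is infinite")
    Inf
  } else if (abs(theta * N - I0) < .Machine$double.eps^0.5 * N) {
    0
  } else {
    log(theta * (N - I0) / ((1 - theta) * I0)) / (C * r * N)
  }
  list(I = I, tau_continuous = tau)
}

#' Fit the logistic conductance to simulated infection curves
#'
#' Least-squares fit of C in the logistic solution to the mean infected
#' count curve of an SI run ensemble (or a single trace). The search uses a
#' log-spaced grid over C in [1e-6, 1] followed by local refinement with
#' `optimize` (residual tolerance 1e-8).
#'
#' @param traces a `diffusion_trace`, a list of traces, or a
#'   `transient_estimate`
#' @param N population size used in the logistic (defaults to the traces'
#'   reachable size)
#' @param r infection rate the curves were simulated with
#' @return list of class `conductance_estimate`: `C`, `fit_residual`,
#'   `mean_curve`
#' @export
fit_conductance <- function(traces, N = NULL, r) {
  if (inherits(traces, "transient_estimate")) traces <- traces$traces
  if (inherits(traces, "diffusion_trace")) traces <- list(traces)
  ok <- !vapply(traces, function(tr) tr$censored, TRUE)
  if (!any(ok)) stop("fit error: no uncensored trace available")
  traces <- traces[ok]
  if (is.null(N)) N <- max(vapply(traces, function(tr) tr$n_reachable, 0))
  L <- max(vapply(traces, function(tr) length(tr$infected_counts), 0L))
  if (L < 3) stop("fit error: need at least 3 time points")
  M <- vapply(traces, function(tr) {
    x <- tr$infected_counts
    c(x, rep(x[length(x)], L - length(x)))
  }, numeric(L))
  curve <- rowMeans(matrix(M, nrow = L))
  if (max(curve) <= curve[1]) stop("fit error: infection curve never grows")
  tt <- seq_len(L) - 1
  I0 <- curve[1]
  sse <- function(C) sum((N * I0 / (I0 + (N - I0) * exp(-C * r * N * tt)) - curve)^2)
  grid <- 10^seq(-6, 0, length.out = 61)
  vals <- vapply(grid, sse, 0)
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(lc) sse(exp(lc)), c(log(lo), log(hi)), tol = 1e-8)
  structure(list(C = exp(opt$minimum), fit_residual = opt$objective,
                 mean_curve = curve),
            class = "conductance_estimate")
}

#' Subgraph/host transient-time scaling diagnostic
#'
#' The ratio (tau(M) * #G) / (tau(G) * #M): equal to 1 when the subgraph's
#' transient time scales with its relative size. Reported as a diagnostic,
#' never asserted, because the logistic solution predicts a ln N / (C r N)
#' scaling instead whenever sub- and supergraph share the same conductance.
#'
#' @param tau_sub,tau_host mean transient times of subgraph and host
#' @param n_sub,n_host node counts of subgraph and host
#' @return the dimensionless scaling ratio
#' @export
scaling_ratio <- function(tau_sub, tau_host, n_sub, n_host) {
  (tau_sub * n_host) / (tau_host * n_sub)
}
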