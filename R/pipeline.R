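#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run. All randomness is derived
#' deterministically from `master_seed`, and the configuration is echoed
#' into the report so a run is fully reproducible from its output.
#'
#' @param methods sampling methods to compare (subset of
#'   [SAMPLER_METHODS])
#' @param size_grid sample sizes (nodes) to sweep
#' @param replicates samples per (host, method, size) cell
#' @param motif_k motif size for the census (3-5)
#' @param overlap_policy disjoint-census policy
#' @param variants motif frequency variants evaluated
#' @param si [si_params()] for the host transient-time estimation
#' @param si_runs SI runs per host (default 10)
#' @param regression a [regression_config()]
#' @param sampler_params shared method parameters (see [sampler_spec()])
#' @param master_seed master seed
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(methods = c("RN", "NBRW"),
                            size_grid = c(10, 20, 30, 40, 50),
                            replicates = 3,
                            motif_k = 4,
                            overlap_policy = "EDGE_DISJOINT",
                            variants = c("JOINT_RATIO", "DISJOINT_RATIO"),
                            si = si_params(),
                            si_runs = 10,
                            regression = regression_config(),
                            sampler_params = list(),
                            master_seed = 1L) {
  methods <- toupper(methods)
  stopifnot(all(methods %in% SAMPLER_METHODS),
            all(variants %in% c("JOINT_RATIO", "DISJOINT_RATIO")),
            inherits(si, "si_params"),
            inherits(regression, "regression_config"))
  check_motif_k(motif_k)
  structure(list(methods = methods, size_grid = sort(as.integer(size_grid)),
                 replicates = as.integer(replicates),
                 motif_k = as.integer(motif_k),
                 overlap_policy = overlap_policy, variants = variants,
                 si = si, si_runs = as.integer(si_runs),
                 regression = regression, sampler_params = sampler_params,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

config_echo <- function(cfg) {
  list(methods = cfg$methods, size_grid = cfg$size_grid,
       replicates = cfg$replicates, motif_k = cfg$motif_k,
       overlap_policy = cfg$overlap_policy, variants = cfg$variants,
       si = list(r = cfg$si$r, theta = cfg$si$theta,
                 seed_policy = cfg$si$seed_policy,
                 max_steps = cfg$si$max_steps),
       si_runs = cfg$si_runs,
       regression = list(n_folds = cfg$regression$n_folds,
                         test_fraction = cfg$regression$test_fraction,
                         boosting_iterations = cfg$regression$boosting_iterations),
       master_seed = cfg$master_seed)
}

#' Run the subgraph-search pipeline end to end
#'
#' For every host graph: the largest component is taken as the operational
#' host; its transient time is estimated over `si_runs` SI runs and its
#' motif census built. For every (method, size, replicate): a sample is
#' drawn, its census built, and the motif deviation delta to the host
#' computed per variant. Feature tables feed one boosted regression per
#' (method, size, variant) cell; finally methods are ranked and a sample
#' size recommended. Failures are isolated per cell and recorded.
#'
#' @param corpus a [generate_corpus()] result, or a named list of igraphs
#' @param cfg a [pipeline_config()]
#' @param outdir optional directory; when given, the JSON report, flat CSV
#'   tables and the recommended best subgraph per host are written there
#' @return list of class `eval_report`: `mse_table`, `r2_table`,
#'   `ranking`, `recommended_method`, `recommended_size`, `host_table`,
#'   `feature_tables`, `failures`, `config`
#' @export
run_pipeline <- function(corpus, cfg = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  graphs <- if (inherits(corpus, "corpus")) corpus$graphs else corpus
  if (length(graphs) == 0) stop("corpus is empty")
  if (is.null(names(graphs)) || any(!nzchar(names(graphs))))
    stop("corpus graphs must be named")
  ms <- cfg$master_seed
  failures <- list()

  # per-host: operational host (largest component), tau, census, frequencies
  hosts <- lapply(names(graphs), function(id) {
    lcc <- largest_component(graphs[[id]])
    if (igraph::vcount(lcc) < max(cfg$size_grid)) {
      failures[[length(failures) + 1]] <<-
        list(stage = "host", id = id,
             message = sprintf("largest component (%d) smaller than max sample size (%d)",
                               igraph::vcount(lcc), max(cfg$size_grid)))
      return(NULL)
    }
    tau <- tryCatch(
      estimate_transient_time(lcc, cfg$si, n_runs = cfg$si_runs,
                              base_seed = derive_seed(ms, "si", id)),
      error = function(e) e)
    if (inherits(tau, "error")) {
      failures[[length(failures) + 1]] <<-
        list(stage = "tau", id = id, message = conditionMessage(tau))
      return(NULL)
    }
    census <- build_census(lcc, k = cfg$motif_k, policy = cfg$overlap_policy,
                           seed = derive_seed(ms, "mis", id))
    freqs <- lapply(setNames(cfg$variants, cfg$variants), function(v)
      suppressWarnings(motif_frequencies(census, v)))
    list(id = id, lcc = lcc, tau = tau, census = census, freqs = freqs)
  })
  hosts <- Filter(Negate(is.null), hosts)
  if (length(hosts) == 0) stop("no usable host graphs")
  host_ids <- vapply(hosts, `[[`, "", "id")
  names(hosts) <- host_ids
  taus <- vapply(hosts, function(h) h$tau$mean_tau, 0)

  # samples and per-sample censuses
  cells <- expand.grid(method = cfg$methods, size = cfg$size_grid,
                       stringsAsFactors = FALSE)
  meta <- list(); censuses <- list(); deltas <- list()
  for (h in hosts) {
    for (ci in seq_len(nrow(cells))) {
      method <- cells$method[ci]; size <- cells$size[ci]
      for (rep in seq_len(cfg$replicates)) {
        tag <- paste(h$id, method, size, rep, sep = "/")
        res <- tryCatch({
          spec <- sampler_spec(method, size,
                               rng_seed = derive_seed(ms, "sample", tag),
                               params = cfg$sampler_params)
          samp <- draw_sample(h$lcc, spec, host_id = h$id)
          cen <- build_census(samp$subgraph, k = cfg$motif_k,
                              policy = cfg$overlap_policy,
                              seed = derive_seed(ms, "mis", tag))
          dl <- lapply(cfg$variants, function(v) {
            sf <- suppressWarnings(motif_frequencies(cen, v))
            motif_mse(h$freqs[[v]], sf)$mean
          })
          list(cen = cen, dl = setNames(unlist(dl), cfg$variants))
        }, error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1]] <-
            list(stage = "sample", id = tag, message = conditionMessage(res))
          next
        }
        i <- length(meta) + 1
        meta[[i]] <- data.frame(host_id = h$id, method = method,
                                sample_size = size, replicate = rep,
                                stringsAsFactors = FALSE)
        censuses[[i]] <- res$cen
        deltas[[i]] <- res$dl
      }
    }
  }
  meta_df <- do.call(rbind, meta)

  # delta (MSE) table: mean over hosts and replicates per cell
  mse_rows <- list()
  for (v in cfg$variants) {
    dvec <- vapply(deltas, `[[`, 0, v)
    agg <- stats::aggregate(dvec,
                            by = list(method = meta_df$method,
                                      sample_size = meta_df$sample_size),
                            FUN = mean)
    agg$variant <- v
    names(agg)[3] <- "mean_delta"
    mse_rows[[v]] <- agg[, c("method", "sample_size", "variant", "mean_delta")]
  }
  mse_table <- do.call(rbind, mse_rows)
  rownames(mse_table) <- NULL

  # regression per (method, size, variant) cell
  feature_tables <- list()
  r2_rows <- list()
  for (v in cfg$variants) {
    ft <- build_feature_table(meta_df, censuses, taus, variant = v)
    feature_tables[[v]] <- ft
    for (ci in seq_len(nrow(cells))) {
      method <- cells$method[ci]; size <- cells$size[ci]
      sub <- ft[ft$method == method & ft$sample_size == size, , drop = FALSE]
      cell_cfg <- cfg$regression
      cell_cfg$model_seed <- derive_seed(ms, "model", method, size, v)
      r2 <- tryCatch(evaluate_prediction(sub, cell_cfg)$mean_r2,
                     error = function(e) e)
      if (inherits(r2, "error")) {
        failures[[length(failures) + 1]] <-
          list(stage = "regression",
               id = paste(method, size, v, sep = "/"),
               message = conditionMessage(r2))
        next
      }
      r2_rows[[length(r2_rows) + 1]] <-
        data.frame(method = method, sample_size = size, variant = v,
                   mean_r2 = r2, stringsAsFactors = FALSE)
    }
  }
  r2_table <- do.call(rbind, r2_rows)

  sel <- rank_and_select(mse_table, r2_table, cfg$size_grid)

  host_table <- data.frame(
    host_id = host_ids,
    n_nodes_lcc = vapply(hosts, function(h) as.integer(igraph::vcount(h$lcc)), 0L),
    mean_tau = taus,
    sd_tau = vapply(hosts, function(h) h$tau$sd_tau, 0),
    n_censored = vapply(hosts, function(h) h$tau$n_censored, 0L),
    stringsAsFactors = FALSE)
  rownames(host_table) <- NULL

  report <- structure(list(
    config = config_echo(cfg),
    host_table = host_table,
    mse_table = mse_table,
    r2_table = r2_table,
    ranking = list(by_delta = sel$ranking_delta, by_r2 = sel$ranking_r2),
    recommended_method = sel$recommended_method,
    recommended_size = sel$recommended_size,
    selection_fallback = sel$fallback,
    feature_tables = feature_tables,
    n_failures = length(failures),
    failures = failures), class = "eval_report")

  if (!is.null(outdir)) {
    write_report(report, hosts, cfg, outdir)
  }
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report\n")
  cat("  hosts:", nrow(x$host_table), " failures:", x$n_failures, "\n")
  cat("  recommended method:", x$recommended_method,
      " size:", x$recommended_size, "\n")
  cat("  ranking by delta:", paste(x$ranking$by_delta, collapse = " > "), "\n")
  cat("  ranking by R2:  ", paste(x$ranking$by_r2, collapse = " > "), "\n")
  invisible(x)
}

report_json <- function(report) {
  jsonlite::toJSON(list(
    config = report$config,
    host_table = report$host_table,
    mse_table = report$mse_table,
    r2_table = report$r2_table,
    ranking = report$ranking,
    recommended_method = report$recommended_method,
    recommended_size = report$recommended_size,
    selection_fallback = report$selection_fallback,
    n_failures = report$n_failures,
    failures = report$failures),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_report <- function(report, hosts, cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeLines(report_json(report), file.path(outdir, "report.json"))
  write.csv(report$mse_table, file.path(outdir, "mse_table.csv"),
            row.names = FALSE)
  write.csv(report$r2_table, file.path(outdir, "r2_table.csv"),
            row.names = FALSE)
  write.csv(report$host_table, file.path(outdir, "hosts.csv"),
            row.names = FALSE)
  for (v in names(report$feature_tables))
    write.csv(report$feature_tables[[v]],
              file.path(outdir, sprintf("features_%s.csv", tolower(v))),
              row.names = FALSE)
  extract_best_subgraphs(lapply(hosts, `[[`, "lcc"),
                         method = report$recommended_method,
                         size = report$recommended_size,
                         master_seed = cfg$master_seed,
                         sampler_params = cfg$sampler_params,
                         outdir = file.path(outdir, "best_subgraphs"))
  invisible(outdir)
}

#' Extract the recommended best subgraph of every host
#'
#' Draws one sample per host with the recommended method and size and
#' writes it as an edge list, plus a JSON sidecar listing each sample's
#' node membership (for highlighting the subgraph inside its host).
#' Hosts smaller than the requested size are skipped with a warning.
#'
#' @param hosts named list of connected host graphs
#' @param method sampler method name
#' @param size sample size in nodes
#' @param master_seed seed the per-host sampling seeds are derived from
#' @param sampler_params shared sampler parameters
#' @param outdir output directory (created if missing); `NULL` returns the
#'   samples without writing
#' @return named list of `sample_result`s, invisibly
#' @export
extract_best_subgraphs <- function(hosts, method, size, master_seed = 1L,
                                   sampler_params = list(), outdir = NULL) {
  if (!is.null(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  membership <- list()
  for (id in names(hosts)) {
    g <- hosts[[id]]
    if (igraph::vcount(g) < size) {
      warning("host ", id, " smaller than recommended size ", size,
              "; skipped")
      next
    }
    spec <- sampler_spec(method, size,
                         rng_seed = derive_seed(master_seed, "extract", id),
                         params = sampler_params)
    samp <- draw_sample(g, spec, host_id = id)
    out[[id]] <- samp
    membership[[id]] <- igraph::V(samp$subgraph)$name
    if (!is.null(outdir))
      write_edge_list(samp$subgraph, file.path(outdir, paste0(id, ".edges")))
  }
  if (!is.null(outdir))
    jsonlite::write_json(membership, file.path(outdir, "membership.json"))
  invisible(out)
}

#' Load a directory of edge-list files as a corpus
#'
#' @param dir directory containing `*.edges` / `*.txt` / `*.tsv` edge lists
#' @param pattern filename regexp
#' @return named list of igraphs (names = file names without extension)
#' @export
load_corpus_dir <- function(dir, pattern = "\\.(edges|txt|tsv)$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0) stop("no edge-list files found in ", dir)
  graphs <- lapply(files, load_edge_list)
  names(graphs) <- sub("\\.[^.]*$", "", basename(files))
  graphs
}
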