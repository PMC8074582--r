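#' Squared deviation between motif frequency vectors
#'
#' The topological goodness criterion: the sum of squared per-class
#' differences between the host's and the sample's motif frequency
#' vectors. The mean (sum divided by the class count) is what the method
#' comparison reports as "MSE".
#'
#' @param freq_host,freq_sample frequency vectors of equal length and class
#'   ordering
#' @return list with `raw` (the squared-deviation sum) and `mean`
#' @export
motif_mse <- function(freq_host, freq_sample) {
  if (length(freq_host) != length(freq_sample))
    stop("frequency vectors differ in length: ", length(freq_host), " vs ",
         length(freq_sample))
  d <- sum((as.numeric(freq_host) - as.numeric(freq_sample))^2)
  list(raw = d, mean = d / length(freq_host))
}

#' Regression protocol configuration
#'
#' Defaults follow the evaluation protocol used throughout the package:
#' gradient-boosted regression trees with 100 boosting iterations
#' (library defaults otherwise), five random shuffle splits with a 30%
#' test fraction, and the coefficient of determination averaged over
#' folds.
#'
#' @param n_folds number of shuffle splits
#' @param test_fraction held-out fraction per split
#' @param boosting_iterations boosting rounds
#' @param model_seed seed for both splits and the booster
#' @return list of class `regression_config`
#' @export
regression_config <- function(n_folds = 5, test_fraction = 0.30,
                              boosting_iterations = 100, model_seed = 1L) {
  stopifnot(n_folds >= 2, test_fraction > 0, test_fraction < 1,
            boosting_iterations >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 test_fraction = test_fraction,
                 boosting_iterations = as.integer(boosting_iterations),
                 model_seed = as.integer(model_seed)),
            class = "regression_config")
}

#' Assemble the motif-feature table for regression
#'
#' One row per sample: the sample's motif class frequencies (fixed class
#' ordering from [motif_class_table()]) under the chosen variant, the
#' disjoint-total scalar, and the host graph's mean transient time as
#' target. Samples with no k-node subgraph at all get an all-zero feature
#' vector and are flagged.
#'
#' @param sample_meta data.frame with columns `host_id`, `method`,
#'   `sample_size` (one row per sample, aligned with `censuses`)
#' @param censuses list of [build_census()] results, one per row
#' @param taus named numeric vector of mean host transient times, indexed
#'   by `host_id`
#' @param variant `"JOINT_RATIO"` or `"DISJOINT_RATIO"` for the per-class
#'   features
#' @return data.frame: metadata columns, feature columns `f_<canon>`,
#'   `disjoint_total`, `zero_flag`, `target_tau`
#' @export
build_feature_table <- function(sample_meta, censuses, taus,
                                variant = c("JOINT_RATIO", "DISJOINT_RATIO")) {
  variant <- match.arg(variant)
  stopifnot(nrow(sample_meta) == length(censuses))
  miss <- setdiff(unique(sample_meta$host_id), names(taus))
  if (length(miss) > 0)
    stop("missing transient-time estimate for host(s): ",
         paste(miss, collapse = ", "))
  k <- censuses[[1]]$k
  classes <- motif_class_table(k)
  feat <- t(vapply(censuses, function(cen) {
    suppressWarnings(c(motif_frequencies(cen, variant),
                       motif_frequencies(cen, "DISJOINT_TOTAL_RATIO")))
  }, numeric(nrow(classes) + 1)))
  colnames(feat) <- c(paste0("f_", classes$canon), "disjoint_total")
  out <- cbind(sample_meta,
               k = k,
               as.data.frame(feat),
               zero_flag = vapply(censuses, function(cen) cen$total_joint == 0,
                                  TRUE),
               target_tau = as.numeric(taus[sample_meta$host_id]))
  rownames(out) <- NULL
  out
}

feature_columns <- function(rows) {
  grep("^f_|^disjoint_total$", names(rows), value = TRUE)
}

#' Predict host transient time from sample motif features
#'
#' The evaluation protocol: `n_folds` random shuffle splits (seeded), each
#' holding out `test_fraction` of the rows; a gradient-boosted tree
#' regressor with `boosting_iterations` rounds fit on the training part;
#' R-squared computed on the held-out part; the mean over folds returned.
#'
#' @param rows a feature table (typically restricted to one method/size
#'   cell) from [build_feature_table()]
#' @param cfg a [regression_config()]
#' @param model `"boosted"` (default) for gradient-boosted trees, or
#'   `"linear"` for an ordinary least-squares baseline with the same split
#'   protocol
#' @return list with `mean_r2` and `fold_r2`
#' @export
evaluate_prediction <- function(rows, cfg = regression_config(),
                                model = c("boosted", "linear")) {
  stopifnot(inherits(cfg, "regression_config"))
  model <- match.arg(model)
  if (nrow(rows) < 20) stop("need at least 20 feature rows")
  y <- rows$target_tau
  if (length(unique(y)) < 2) stop("evaluation error: constant target")
  X <- as.matrix(rows[, feature_columns(rows), drop = FALSE])
  n <- nrow(X)
  n_test <- max(1L, round(cfg$test_fraction * n))
  fold_r2 <- vapply(seq_len(cfg$n_folds), function(f) {
    set.seed(cfg$model_seed + f)
    test <- sample.int(n, n_test)
    pred <- if (model == "boosted") {
      fit <- xgboost::xgboost(
        X[-test, , drop = FALSE], y[-test],
        nrounds = cfg$boosting_iterations,
        objective = "reg:squarederror",
        verbosity = 0, nthreads = 1,
        seed = cfg$model_seed + f)
      stats::predict(fit, X[test, , drop = FALSE])
    } else {
      df <- as.data.frame(X)
      df$..y <- y
      fit <- stats::lm(..y ~ ., data = df[-test, , drop = FALSE])
      stats::predict(fit, df[test, , drop = FALSE])
    }
    1 - sum((y[test] - pred)^2) / sum((y[test] - mean(y[test]))^2)
  }, 0)
  list(mean_r2 = mean(fold_r2), fold_r2 = fold_r2)
}

#' Rank sampling methods and recommend a sample size
#'
#' Methods are ranked ascending by their mean motif deviation (delta) and
#' descending by mean R-squared, each averaged over sizes and variants.
#' The recommended method is the first one present in both top-5 lists
#' (smallest worst rank; ties broken by the delta rank). The recommended
#' size is the smallest grid size after which both criteria plateau: the
#' absolute change to the next size falls below `plateau_frac` of the
#' criterion's range over the grid, for the recommended method.
#'
#' @param mse_table data.frame with columns `method`, `sample_size`,
#'   `variant`, `mean_delta`
#' @param r2_table data.frame with columns `method`, `sample_size`,
#'   `variant`, `mean_r2`
#' @param size_grid sizes the tables cover
#' @param plateau_frac plateau threshold as a fraction of the range
#'   (default 0.10)
#' @return list with `ranking_delta`, `ranking_r2`, `recommended_method`,
#'   `recommended_size`, `fallback` (TRUE when the top-5 lists were
#'   disjoint and the best-R2 method was used)
#' @export
rank_and_select <- function(mse_table, r2_table, size_grid,
                            plateau_frac = 0.10) {
  agg_d <- stats::aggregate(mean_delta ~ method, mse_table, mean)
  rank_d <- agg_d$method[order(agg_d$mean_delta)]
  if (is.null(r2_table) || nrow(r2_table) == 0) {
    warning("no regression results available; ranking by delta only")
    size_grid <- sort(size_grid)
    return(list(ranking_delta = rank_d, ranking_r2 = character(0),
                recommended_method = rank_d[1],
                recommended_size = max(size_grid), fallback = TRUE))
  }
  agg_r <- stats::aggregate(mean_r2 ~ method, r2_table, mean)
  rank_r <- agg_r$method[order(-agg_r$mean_r2)]
  top_d <- head(rank_d, 5)
  top_r <- head(rank_r, 5)
  inter <- intersect(top_d, top_r)
  fallback <- length(inter) == 0
  if (fallback) {
    warning("top-5 lists by delta and R2 are disjoint; falling back to the best-R2 method")
    method <- rank_r[1]
  } else {
    worst <- vapply(inter, function(m)
      max(match(m, rank_d), match(m, rank_r)), 0)
    tie <- inter[worst == min(worst)]
    method <- tie[order(match(tie, rank_d))][1]
  }
  size_grid <- sort(size_grid)
  sel_size <- max(size_grid)
  if (length(size_grid) > 1) {
    curve_d <- vapply(size_grid, function(s)
      mean(mse_table$mean_delta[mse_table$method == method &
                                  mse_table$sample_size == s]), 0)
    curve_r <- vapply(size_grid, function(s)
      mean(r2_table$mean_r2[r2_table$method == method &
                              r2_table$sample_size == s]), 0)
    rng_d <- diff(range(curve_d, na.rm = TRUE))
    rng_r <- suppressWarnings(diff(range(curve_r, na.rm = TRUE)))
    for (i in seq_len(length(size_grid) - 1)) {
      dd <- abs(curve_d[i + 1] - curve_d[i])
      dr <- abs(curve_r[i + 1] - curve_r[i])
      ok_d <- is.na(dd) || rng_d == 0 || dd < plateau_frac * rng_d
      ok_r <- is.na(dr) || !is.finite(rng_r) || rng_r == 0 ||
        dr < plateau_frac * rng_r
      if (ok_d && ok_r) {
        sel_size <- size_grid[i]
        break
      }
    }
  }
  list(ranking_delta = rank_d, ranking_r2 = rank_r,
       recommended_method = method, recommended_size = sel_size,
       fallback = fallback)
}
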