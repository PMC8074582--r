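test_that("motif deviation delta matches hand arithmetic", {
  expect_equal(motif_mse(c(1, 0), c(1, 0))$raw, 0)
  expect_equal(motif_mse(c(1, 0), c(0, 1))$raw, 2)
  expect_equal(motif_mse(c(1, 0), c(0, 1))$mean, 1)
  d <- motif_mse(c(0.7, 0.3), c(0.5, 0.5))
  expect_equal(d$raw, 0.08)
  expect_equal(d$mean, 0.04)
  expect_error(motif_mse(c(1, 0), c(1, 0, 0)), "length")
})

test_that("delta is symmetric, non-negative and zero only at equality", {
  set.seed(4)
  for (i in 1:20) {
    a <- runif(7); b <- runif(7)
    expect_equal(motif_mse(a, b)$raw, motif_mse(b, a)$raw)
    expect_gte(motif_mse(a, b)$raw, 0)
    if (!isTRUE(all.equal(a, b))) expect_gt(motif_mse(a, b)$raw, 0)
  }
  fx <- fixture_graphs()
  for (nm in names(fx)) {
    g <- fx[[nm]]
    if (igraph::vcount(g) < 3) next
    f <- suppressWarnings(motif_frequencies(build_census(g, 3, seed = 1)))
    expect_equal(motif_mse(f, f)$raw, 0)
  }
})

test_that("feature tables have the fixed class layout and flag empty censuses", {
  fx <- fixture_graphs()
  meta <- data.frame(host_id = c("a", "b"), method = "RN", sample_size = 5,
                     replicate = 1)
  cens <- list(build_census(fx$K10, 4, seed = 1),
               build_census(fx$path10, 4, seed = 1))
  taus <- c(a = 3.5, b = 9)
  ft <- build_feature_table(meta, cens, taus, "JOINT_RATIO")
  expect_equal(nrow(ft), 2)
  expect_equal(length(feature_columns(ft)), 7) # 6 classes + disjoint total
  expect_equal(ft$target_tau, c(3.5, 9))
  expect_false(any(ft$zero_flag))

  # sparse sample with no 4-node subgraph -> zero features, flagged
  pair <- igraph::make_ring(3)
  igraph::V(pair)$name <- as.character(1:3)
  cens2 <- list(build_census(fx$K10, 4, seed = 1),
                suppressWarnings(build_census(pair, 4, seed = 1)))
  ft2 <- suppressWarnings(build_feature_table(meta, cens2, taus, "JOINT_RATIO"))
  expect_true(ft2$zero_flag[2])
  expect_equal(sum(ft2[2, feature_columns(ft2)]), 0)

  expect_error(build_feature_table(meta, cens, c(a = 1), "JOINT_RATIO"),
               "missing transient-time")
})

test_that("a leaked target feature gives near-perfect R2", {
  set.seed(11)
  n_hosts <- 60
  rows <- data.frame(host_id = rep(paste0("h", 1:n_hosts), 3), method = "RN",
                     sample_size = 10,
                     f_leak = rep(runif(n_hosts) * 10, 3),
                     disjoint_total = runif(3 * n_hosts))
  rows$target_tau <- rows$f_leak
  r <- evaluate_prediction(rows, regression_config(model_seed = 5))
  expect_gte(r$mean_r2, 0.99)
})

test_that("permuted targets give no predictive power", {
  set.seed(12)
  n <- 60
  rows <- data.frame(host_id = rep(letters[1:20], 3), method = "RN",
                     sample_size = 10,
                     f_a = runif(n), f_b = runif(n), disjoint_total = runif(n),
                     target_tau = rep(runif(20) * 10, 3))
  r2s <- vapply(1:10, function(i) {
    set.seed(100 + i)
    perm <- rows
    perm$target_tau <- sample(perm$target_tau)
    evaluate_prediction(perm, regression_config(model_seed = i))$mean_r2
  }, 0)
  expect_lte(mean(r2s), 0.1)
})

test_that("the evaluation protocol is reproducible under a fixed seed", {
  set.seed(13)
  rows <- data.frame(host_id = rep(letters[1:20], 2), method = "RN",
                     sample_size = 10,
                     f_a = runif(40), disjoint_total = runif(40),
                     target_tau = runif(40))
  r1 <- evaluate_prediction(rows, regression_config(model_seed = 9))
  r2 <- evaluate_prediction(rows, regression_config(model_seed = 9))
  expect_identical(r1$fold_r2, r2$fold_r2)
})

test_that("protocol guards reject unusable inputs", {
  rows <- data.frame(host_id = "a", method = "RN", sample_size = 10,
                     f_a = 1, disjoint_total = 1, target_tau = 1)
  expect_error(evaluate_prediction(rows), "at least 20")
  rows <- rows[rep(1, 25), ]
  expect_error(evaluate_prediction(rows), "constant target")
})

test_that("method ranking and selection follow both criteria", {
  grid <- c(10, 20, 30, 40)
  mk_tables <- function(deltas, r2s) {
    mse <- expand.grid(method = names(deltas), sample_size = grid,
                       variant = "JOINT_RATIO", stringsAsFactors = FALSE)
    mse$mean_delta <- deltas[mse$method]
    r2 <- expand.grid(method = names(r2s), sample_size = grid,
                      variant = "JOINT_RATIO", stringsAsFactors = FALSE)
    r2$mean_r2 <- r2s[r2$method]
    list(mse = mse, r2 = r2)
  }
  # method A best in both -> A
  tb <- mk_tables(c(A = 0.01, B = 0.05, C = 0.1),
                  c(A = 0.9, B = 0.5, C = 0.1))
  sel <- rank_and_select(tb$mse, tb$r2, grid)
  expect_equal(sel$recommended_method, "A")
  expect_false(sel$fallback)

  # disjoint top-5 lists -> warning + best-R2 fallback
  methods <- paste0("M", 1:10)
  d <- setNames(seq(0.01, 0.1, length.out = 10), methods)
  r <- setNames(seq(0.9, 0.1, length.out = 10), rev(methods))
  tb <- mk_tables(d, r)
  expect_warning(sel <- rank_and_select(tb$mse, tb$r2, grid), "disjoint")
  expect_true(sel$fallback)
  expect_equal(sel$recommended_method, "M10") # best R2
})

test_that("size recommendation finds the plateau", {
  grid <- c(10, 20, 30, 40, 50)
  mse <- expand.grid(method = "A", sample_size = grid,
                     variant = "JOINT_RATIO", stringsAsFactors = FALSE)
  # steep drop until 30, flat after
  mse$mean_delta <- c(0.10, 0.05, 0.01, 0.0095, 0.009)
  r2 <- mse; names(r2)[4] <- "mean_r2"
  r2$mean_r2 <- c(0.2, 0.5, 0.8, 0.81, 0.815)
  r2$mean_delta <- NULL
  sel <- rank_and_select(mse, r2, grid)
  expect_equal(sel$recommended_size, 30)
})
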