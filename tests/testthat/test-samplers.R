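fx <- fixture_graphs()

test_that("identical seeds reproduce identical samples for every method", {
  g <- largest_component(er_graph(60, 0.08, 3))
  for (m in SAMPLER_METHODS) {
    s1 <- draw_sample(g, sampler_spec(m, 12, rng_seed = 77))
    s2 <- draw_sample(g, sampler_spec(m, 12, rng_seed = 77))
    expect_setequal(igraph::V(s1$subgraph)$name, igraph::V(s2$subgraph)$name)
    expect_equal(igraph::ecount(s1$subgraph), igraph::ecount(s2$subgraph))
  }
})

test_that("samples are contained in the host and hit the target size", {
  set.seed(991)
  cases <- data.frame(n = sample(40:80, 10, replace = TRUE),
                      p = runif(10, 0.08, 0.2),
                      seed = sample.int(1e6, 10))
  for (i in seq_len(nrow(cases))) {
    g <- largest_component(er_graph(cases$n[i], cases$p[i], cases$seed[i]))
    for (m in SAMPLER_METHODS) {
      tgt <- 10
      s <- draw_sample(g, sampler_spec(m, tgt, rng_seed = cases$seed[i] + 1),
                       host_id = "h")
      expect_subgraph_of(s$subgraph, g)
      if (m == "RE") expect_true(s$actual_size %in% c(tgt, tgt + 1))
      else expect_equal(s$actual_size, tgt)
    }
  }
})

test_that("full-size samples return the whole host", {
  g <- fx$K10
  for (m in c("RN", "PRN", "SB", "CSE", "RW", "NBRW")) {
    s <- draw_sample(g, sampler_spec(m, 10, rng_seed = 5))
    expect_setequal(igraph::V(s$subgraph)$name, igraph::V(g)$name)
    expect_equal(igraph::ecount(s$subgraph), igraph::ecount(g))
  }
})

test_that("oversized requests and unknown methods are rejected", {
  expect_error(draw_sample(fx$triangle, sampler_spec("RN", 5)), "exceeds")
  expect_error(sampler_spec("BOGUS", 5), "unknown sampling method")
  expect_error(sampler_spec("RWJ", 5, params = list(p = 1.5)), "jump probability")
})

test_that("degree-proportional sampling favours the hub at the exact rate", {
  # star: hub degree 9, leaves degree 1. For a 2-node degree-proportional
  # sample, P(hub included) = 1 - (9/18)(8/17) = 13/17 (exact enumeration).
  hub_in <- vapply(1:2000, function(s) {
    smp <- draw_sample(fx$star10, sampler_spec("DEGREE", 2, rng_seed = s))
    "1" %in% igraph::V(smp$subgraph)$name
  }, TRUE)
  expect_equal(mean(hub_in), 13 / 17, tolerance = 0.035)
})

test_that("random-edge sampling returns sampled edges, not the induced graph", {
  s <- draw_sample(fx$triangle, sampler_spec("RE", 3, rng_seed = 2))
  expect_equal(s$actual_size, 3)
  expect_equal(igraph::ecount(s$subgraph), 2) # two edges of a triangle cover it

  s <- draw_sample(largest_component(er_graph(50, 0.1, 4)),
                   sampler_spec("RE", 3, rng_seed = 9))
  expect_equal(igraph::degree(s$subgraph) > 0,
               rep(TRUE, igraph::vcount(s$subgraph)),
               ignore_attr = TRUE) # every node touches a sampled edge
})

test_that("snowball on a path is a BFS prefix and CSE finds the hub", {
  # path: SB from an end collects a contiguous prefix
  s <- draw_sample(fx$path10, sampler_spec("SB", 4, rng_seed = 1))
  nodes <- as.integer(igraph::V(s$subgraph)$name)
  expect_equal(max(nodes) - min(nodes), 3) # contiguous on the path
  expect_true(igraph::is_connected(s$subgraph))

  # star: any CSE run must include the hub by step 2
  for (sd in 1:5) {
    s <- draw_sample(fx$star10, sampler_spec("CSE", 3, rng_seed = sd))
    expect_true("1" %in% igraph::V(s$subgraph)$name)
  }
})

test_that("exploration samples are connected", {
  g <- largest_component(er_graph(70, 0.07, 12))
  for (m in c("SB", "CSE", "SP")) {
    for (sd in 1:5) {
      s <- draw_sample(g, sampler_spec(m, 15, rng_seed = sd))
      expect_true(igraph::is_connected(s$subgraph),
                  label = paste(m, "seed", sd, "connected"))
    }
  }
})

test_that("NBRW never backtracks except at degree-1 nodes", {
  g <- largest_component(er_graph(40, 0.06, 21))
  deg <- igraph::degree(g)
  for (sd in 1:5) {
    s <- draw_sample(g, sampler_spec("NBRW", 15, rng_seed = sd,
                                     params = list(keep_trace = TRUE)))
    tr <- s$trace
    for (i in seq_len(length(tr) - 2)) {
      if (any(is.na(tr[i:(i + 2)]))) next # restart marker
      if (tr[i + 2] == tr[i]) {
        expect_equal(deg[[tr[i + 1]]], 1,
                     label = sprintf("backtrack at %s only allowed for degree 1",
                                     tr[i + 1]))
      }
    }
  }
})

test_that("NBRW sweeps a cycle without reversing", {
  s <- draw_sample(fx$cycle6, sampler_spec("NBRW", 6, rng_seed = 2,
                                           params = list(keep_trace = TRUE)))
  expect_equal(length(s$trace), 6) # 6 distinct nodes in 5 steps, no repeats
  expect_equal(anyDuplicated(s$trace), 0)
})

test_that("NBRW backtracks through a path end and collects all of a 3-path", {
  path3 <- induced_on(fx$path10, c("1", "2", "3"))
  for (sd in 1:5) {
    s <- draw_sample(path3, sampler_spec("NBRW", 3, rng_seed = sd))
    expect_setequal(igraph::V(s$subgraph)$name, c("1", "2", "3"))
  }
})

test_that("walk samples contain their connected walk trace", {
  g <- largest_component(er_graph(50, 0.1, 31))
  for (m in c("RW", "MHRW", "RWJ", "NBRW")) {
    s <- draw_sample(g, sampler_spec(m, 12, rng_seed = 3,
                                     params = list(keep_trace = TRUE)))
    expect_setequal(unique(s$trace[!is.na(s$trace)]),
                    igraph::V(s$subgraph)$name)
  }
})

test_that("MHRW visits are uniform and RW visits degree-proportional", {
  g <- largest_component(er_graph(30, 0.2, 3))
  nv <- igraph::vcount(g)
  fr_mh <- walk_visit_frequencies(g, "MHRW", 5e5, rng_seed = 11)
  tv_mh <- 0.5 * sum(abs(fr_mh - 1 / nv))
  expect_lt(tv_mh, 0.05)

  fr_rw <- walk_visit_frequencies(g, "RW", 5e5, rng_seed = 12)
  pi_rw <- igraph::degree(g) / (2 * igraph::ecount(g))
  tv_rw <- 0.5 * sum(abs(fr_rw - pi_rw))
  expect_lt(tv_rw, 0.05)
})
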