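test_that("propagator conserves probability and matches a dense expm", {
  a <- random_connected_graph(8, seed = 41)
  g <- build_graph(a > 0, a + diag(8))
  for (t in c(0, 0.1, 1, 10)) {
    e <- graph_propagator(g, t)
    expect_equal(rowSums(e), rep(1, 8), tolerance = 1e-10)
  }
  skip_if_not_installed("Matrix")
  e1 <- graph_propagator(g, 0.7)
  e2 <- as.matrix(Matrix::expm(-0.7 * g$laplacian))
  expect_equal(e1, e2, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("block autocovariance analytic cases", {
  a <- random_connected_graph(4, seed = 42)
  g <- build_graph(a > 0, a + diag(4))
  # one-block partition: R = [0] at any t (probability conservation)
  for (t in c(0, 0.5, 3)) {
    expect_equal(as.vector(block_autocovariance(g, rep(1, 4), t)), 0,
                 tolerance = 1e-12)
  }
  # t = 0, singletons, uniform pi, N = 4: trace = 1 - 1/4
  r0 <- block_autocovariance(g, 1:4, 0)
  expect_equal(sum(diag(r0)), 0.75, tolerance = 1e-12)
  # t large: mixing drives every entry to 0
  a6 <- random_connected_graph(6, seed = 43)
  g6 <- build_graph(a6 > 0, a6 + diag(6))
  r <- block_autocovariance(g6, c(1, 1, 2, 2, 3, 3), 1e3)
  expect_lt(sum(abs(diag(r))), 1e-6)
  expect_error(block_autocovariance(g, 1:4, -1), "nonnegative")
})

test_that("stability equals a naive loop minimum over the tau grid", {
  a <- random_connected_graph(8, seed = 44)
  g <- build_graph(a > 0, a + diag(8))
  set.seed(44)
  part <- sample(1:3, 8, replace = TRUE)
  grid <- 10^seq(-1.5, 1, length.out = 12)
  for (t in grid[c(3, 7, 12)]) {
    naive <- min(vapply(grid[grid <= t], function(tau)
      sum(diag(block_autocovariance(g, part, tau))), 0))
    expect_equal(stability(g, part, t, tau_grid = grid), naive,
                 tolerance = 1e-12)
  }
  # one-block partition scores 0 at every t
  for (t in grid) expect_equal(stability(g, rep(1, 8), t, grid), 0,
                               tolerance = 1e-12)
  # non-increasing in t for fixed H (min over a growing set)
  vals <- vapply(grid, function(t) stability(g, part, t, grid), 0)
  expect_true(all(diff(vals) <= 1e-12))
  expect_error(stability(g, part, 1, numeric(0)), "non-empty")
})

test_that("louvain recovers planted two-clique structure and the exhaustive optimum", {
  g <- two_clique_graph(4)
  p <- louvain_optimise(g, t = 1, seed = 2)
  expect_equal(p$n_communities, 2L)
  expect_equal(unname(p$labels[1:4]), rep(p$labels[[1]], 4))
  expect_equal(unname(p$labels[5:8]), rep(p$labels[[5]], 4))
  # matches exhaustive search over all 4140 partitions of 8 nodes
  b <- stability_matrix(g, 1)
  ex <- exhaustive_best_partition(b)
  expect_equal(trace_block_sum_r(b, p$labels), ex$score, tolerance = 1e-12)
})

test_that("louvain matches the exhaustive oracle on K5 at large t", {
  a <- matrix(1, 5, 5); diag(a) <- 0
  g <- build_graph(a > 0, a + diag(5))
  b <- stability_matrix(g, 5)
  ex <- exhaustive_best_partition(b)
  p <- louvain_optimise(g, t = 5, seed = 1)
  expect_equal(trace_block_sum_r(b, p$labels), ex$score, tolerance = 1e-14)
  # for an unstructured clique the optimum is the all-singletons partition
  expect_equal(length(unique(ex$labels)), 5L)
})

test_that("louvain is deterministic under a fixed seed", {
  a <- random_connected_graph(20, seed = 45)
  g <- build_graph(a > 0, a + diag(20))
  p1 <- louvain_optimise(g, t = 2, seed = 99)
  p2 <- louvain_optimise(g, t = 2, seed = 99)
  expect_identical(p1$labels, p2$labels)
})

test_that("louvain matches exhaustive search on random weighted graphs", {
  parts8 <- set_partitions(8L)
  masks8 <- partition_pair_masks(parts8, 8L)
  hits <- 0L; total <- 0L
  for (rep in 1:20) {
    a <- random_connected_graph(8, seed = 500 + rep)
    g <- build_graph(a > 0, a + diag(8))
    for (t in c(0.5, 2, 8)) {
      b <- stability_matrix(g, t)
      ex <- exhaustive_best_partition(b, parts8, masks8)
      best <- -Inf
      for (s in 1:5) {
        p <- louvain_optimise(g, t = t, seed = s)
        best <- max(best, trace_block_sum_r(b, p$labels))
      }
      total <- total + 1L
      if (best >= ex$score - 1e-10) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("scan_markov_times is self-consistent and handles degenerate cases", {
  g <- two_clique_graph(4)
  grid <- 10^seq(-1, 1, length.out = 8)
  sc <- scan_markov_times(g, grid, n_restarts = 10, seed = 7)
  expect_s3_class(sc, "ms_scan")
  k <- 6L  # mid-range time: planted 2-way structure
  expect_equal(sc$n_communities[k], 2L)
  expect_equal(sc$r_star[k],
               stability(g, sc$best[[k]], grid[k], tau_grid = grid),
               tolerance = 1e-12)
  expect_true(all(sc$vi_t >= 0 & sc$vi_t <= 1))
  expect_equal(sc$vi_cross, t(sc$vi_cross))
  expect_equal(diag(sc$vi_cross), rep(0, 8))

  # n_restarts = 1: the ensemble pair sum is empty, VI(t) = 0
  sc1 <- scan_markov_times(g, grid, n_restarts = 1, seed = 3)
  expect_equal(sc1$vi_t, rep(0, 8))

  # single grid point: vi_cross is the 1x1 zero matrix
  sc0 <- scan_markov_times(g, 1, n_restarts = 3, seed = 3)
  expect_equal(sc0$vi_cross, matrix(0, 1, 1))
})

test_that("scan rejects invalid grids", {
  g <- two_clique_graph(3)
  expect_error(scan_markov_times(g, c(2, 1)), "increasing")
  expect_error(scan_markov_times(g, c(-1, 1)), "increasing and positive")
  expect_error(scan_markov_times(g, 1:3, n_restarts = 0), ">= 1")
})
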