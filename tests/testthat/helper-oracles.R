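# Independent oracles and shared fixtures for the test suite.
# Oracles are deliberately naive (enumeration / brute force) and share no
# code with the implementation paths they check.

# --- DTW: exhaustive monotone warping-path enumeration -----------------------
dtw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + (x[i] - y[j])^2
    if (acc >= best) return(invisible(NULL))
    if (i == n && j == m) {
      best <<- acc
      return(invisible(NULL))
    }
    if (i < n) recurse(i + 1L, j, acc)
    if (j < m) recurse(i, j + 1L, acc)
    if (i < n && j < m) recurse(i + 1L, j + 1L, acc)
    invisible(NULL)
  }
  recurse(1L, 1L, 0)
  best
}

# --- set partitions of n elements as restricted growth strings ---------------
set_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, mx) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(mx + 1L)) grow(c(prefix, v), max(mx, v))
    invisible(NULL)
  }
  grow(1L, 1L)
  out
}

# pair-equality mask matrix: one row per partition, columns vec(outer ==)
partition_pair_masks <- function(parts, n) {
  t(vapply(parts, function(p) as.numeric(outer(p, p, `==`)), numeric(n * n)))
}

# exhaustive maximiser of Tr[H^T B H] over all partitions
exhaustive_best_partition <- function(B, parts = NULL, masks = NULL) {
  n <- nrow(B)
  if (is.null(parts)) parts <- set_partitions(n)
  if (is.null(masks)) masks <- partition_pair_masks(parts, n)
  scores <- as.vector(masks %*% as.vector(B))
  list(score = max(scores), labels = parts[[which.max(scores)]],
       scores = scores)
}

# R-side mirror of the optimised objective Tr[H^T B H]
trace_block_sum_r <- function(b, lab) {
  sum(b[outer(lab, lab, `==`)])
}

# --- MST brute force over all spanning trees (N <= 6) ------------------------
mst_weight_oracle <- function(dist) {
  n <- nrow(dist)
  pairs <- which(upper.tri(dist), arr.ind = TRUE)
  combs <- utils::combn(nrow(pairs), n - 1L)
  best <- Inf
  for (c in seq_len(ncol(combs))) {
    sel <- pairs[combs[, c], , drop = FALSE]
    g <- igraph::graph_from_edgelist(sel, directed = FALSE)
    if (igraph::vcount(g) < n) next
    if (igraph::is_connected(g)) {
      w <- sum(dist[sel])
      if (w < best) best <- w
    }
  }
  best
}

# --- isotonic regression: brute force over contiguous blockings --------------
isotonic_oracle <- function(y) {
  n <- length(y)
  if (n == 1L) return(as.numeric(y))
  best <- NULL; best_sse <- Inf
  for (code in 0:(2^(n - 1L) - 1L)) {
    cuts <- as.logical(bitwAnd(code, 2^(0:(n - 2L))))
    grp <- cumsum(c(1L, as.integer(cuts)))
    levels <- tapply(y, grp, mean)
    if (any(diff(levels) < 0)) next
    fit <- levels[grp]
    sse <- sum((y - fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- as.numeric(fit)
    }
  }
  best
}

# --- hypergeometric upper tail by subset enumeration (pop <= 12) -------------
enrichment_oracle <- function(cluster_size, cluster_hits, population,
                              population_hits) {
  subsets <- utils::combn(population, cluster_size)
  hits <- seq_len(population_hits)
  count <- sum(apply(subsets, 2, function(s) sum(s %in% hits) >= cluster_hits))
  count / ncol(subsets)
}

# --- toy graphs --------------------------------------------------------------
two_clique_graph <- function(clique = 4L, bridge_weight = 1) {
  n <- 2L * clique
  a <- matrix(0, n, n)
  a[seq_len(clique), seq_len(clique)] <- 1
  a[(clique + 1):n, (clique + 1):n] <- 1
  diag(a) <- 0
  a[clique, clique + 1L] <- bridge_weight
  a[clique + 1L, clique] <- bridge_weight
  build_graph(a > 0, a + diag(n))
}

random_connected_graph <- function(n, seed) {
  set.seed(seed)
  repeat {
    a <- matrix(0, n, n)
    up <- which(upper.tri(a))
    on <- runif(length(up)) < 0.5
    a[up[on]] <- runif(sum(on), 0.2, 1)
    a <- a + t(a)
    g <- igraph::graph_from_adjacency_matrix(a > 0, mode = "undirected")
    if (igraph::is_connected(g) && all(rowSums(a) > 0)) break
  }
  a
}

# --- shared planted-archetype cohort (memoised: DTW reused across tests) -----
.fixture_env <- new.env(parent = emptyenv())

planted_fixture <- function() {
  if (!is.null(.fixture_env$planted)) return(.fixture_env$planted)
  cur <- make_curriculum(376L, 3L, 70)
  cohort <- simulate_cohort(cur, c(early_bird = 20, on_time = 20,
                                   low_engager = 20, crammer = 20),
                            seed = 20L)
  series <- as_event_series(cohort)
  ps <- pairwise_similarity(series)
  .fixture_env$planted <- list(cohort = cohort, series = series,
                               dist = ps$dist, sim = ps$sim,
                               sigma = ps$sigma, labels = cohort$labels)
  .fixture_env$planted
}

planted_scan <- function(gamma = 0.5) {
  key <- paste0("scan_", gamma)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  fx <- planted_fixture()
  mask <- rmst_sparsify(fx$dist, rmst_config(gamma, 1L))
  g <- build_graph(mask, fx$sim)
  sc <- scan_markov_times(g, n_restarts = 100L, seed = 11L)
  .fixture_env[[key]] <- sc
  sc
}
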