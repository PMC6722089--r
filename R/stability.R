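#' Generalized stability matrix B(t)
#'
#' \eqn{B(t) = \Pi e^{-tL} - \pi^T \pi} with \eqn{\Pi = diag(\pi)}. The
#' quality of a partition with membership matrix H at Markov time t is
#' \eqn{Tr[H^T B(t) H]}, the probability that a random walker at
#' stationarity remains within its starting community over horizon t, in
#' excess of chance.
#'
#' @param graph `learner_graph`.
#' @param t Nonnegative Markov time.
#' @return Dense N x N matrix.
#' @export
stability_matrix <- function(graph, t) {
  e <- graph_propagator(graph, t)
  graph$pi * e - outer(graph$pi, graph$pi)
}

#' Block autocovariance matrix of a partition
#'
#' \eqn{R(t; H) = H^T (\Pi e^{-tL} - \pi^T \pi) H}: entry (a, b) is the
#' probability (in excess of chance) that a walker starting in community a
#' is found in community b after Markov time t. Diagonal entries measure
#' containment; the trace is the instantaneous partition quality.
#'
#' @param graph `learner_graph`.
#' @param partition Community labels (integer vector, one per node) or a
#'   `partition` object.
#' @param t Nonnegative Markov time.
#' @return c x c matrix.
#' @export
block_autocovariance <- function(graph, partition, t) {
  if (!is.finite(t) || t < 0) stop("`t` must be nonnegative")
  lab <- partition_labels(partition)
  n <- nrow(graph$adjacency)
  if (length(lab) != n) stop("partition length must match graph size")
  b <- stability_matrix(graph, t)
  h <- membership_matrix(lab)
  t(h) %*% b %*% h
}

membership_matrix <- function(lab) {
  lab <- as.integer(factor(lab))
  h <- matrix(0, length(lab), max(lab))
  h[cbind(seq_along(lab), lab)] <- 1
  h
}

partition_labels <- function(partition) {
  if (inherits(partition, "partition")) partition$labels
  else if (is.atomic(partition)) partition
  else stop("`partition` must be a label vector or partition object")
}

#' Markov Stability of a partition
#'
#' \eqn{r(t, H) = \min_{\tau \le t} Tr[R(\tau, H)]}: the worst-case
#' containment of the partition over all Markov times up to t, evaluated on
#' the supplied grid. Non-increasing in t for fixed H; identically 0 for
#' the one-block partition (probability conservation).
#'
#' @param graph `learner_graph`.
#' @param partition Community labels or `partition` object.
#' @param t Markov time.
#' @param tau_grid Grid of candidate times; the minimum is taken over grid
#'   points `<= t` (at least one required — at the first grid point the
#'   minimum is taken at t itself).
#' @return Scalar stability value.
#' @export
stability <- function(graph, partition, t, tau_grid = t) {
  if (length(tau_grid) == 0L) stop("`tau_grid` must be non-empty")
  taus <- tau_grid[tau_grid <= t + 1e-12]
  if (length(taus) == 0L) taus <- t
  lab <- as.integer(factor(partition_labels(partition)))
  min(vapply(taus, function(tau)
    trace_block_sum(stability_matrix(graph, tau), lab), 0))
}

#' Louvain optimisation of Markov Stability at one Markov time
#'
#' Greedy maximisation of \eqn{Tr[H^T B(t) H]}: repeated node-moving sweeps
#' (each node moves to the community with the largest gain, ties broken
#' toward the lower community id) until a local optimum, then aggregation
#' of communities into super-nodes, iterated until no further gain. The
#' node visit order is shuffled by `seed`; identical seeds give identical
#' partitions. B is rescaled to max|B| = 1 internally so the strict-gain
#' threshold is scale-free.
#'
#' @param graph `learner_graph`, or a precomputed dense B matrix.
#' @param t Markov time (ignored when `graph` is already a B matrix).
#' @param seed Integer seed for the visit-order shuffle.
#' @return `partition` object: `labels` (1-based contiguous ids, named by
#'   learner id when available), `n_communities`, `t`, `seed`.
#' @export
louvain_optimise <- function(graph, t = 1, seed = 1L) {
  if (inherits(graph, "learner_graph")) {
    if (!is.finite(t) || t <= 0) stop("`t` must be positive")
    b <- stability_matrix(graph, t)
    ids <- graph$ids
  } else if (is.matrix(graph)) {
    b <- graph
    ids <- rownames(b)
  } else stop("`graph` must be a learner_graph or a matrix")
  s <- max(abs(b))
  if (s > 0) b <- b / s
  lab <- louvain_dense_impl(b, as.integer(seed))
  if (!is.null(ids)) names(lab) <- ids
  structure(list(labels = lab, n_communities = max(lab),
                 t = t, seed = as.integer(seed)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("Partition: %d communities over %d nodes\n",
              x$n_communities, length(x$labels)))
  invisible(x)
}

#' Scan Markov times: multiscale partitioning with robustness diagnostics
#'
#' For each Markov time t on the grid the Louvain optimiser is run
#' `n_restarts` times from seeded shuffled starts; each optimised partition
#' is scored by the stability r(t, H) (minimum trace over grid times up to
#' t) and the best is kept. Two robustness diagnostics are recorded: VI(t),
#' the mean pairwise variation of information across the restart ensemble
#' (low = the optimiser consistently finds the same partition), and
#' VI(t, t'), the cross-time VI between best partitions (low-VI diagonal
#' blocks = partitions persistent across scales).
#'
#' @param graph `learner_graph`.
#' @param t_grid Increasing positive Markov times; default 100 log-spaced
#'   points in `[1e-2, 1e2]`.
#' @param n_restarts Louvain restarts per time (ensemble size).
#' @param seed Master seed; per-(t, restart) seeds are derived from it.
#' @param progress Print progress every 10 grid points.
#' @return `ms_scan` object with fields `t_grid`, `best` (list of label
#'   vectors), `r_star`, `n_communities`, `vi_t`, `vi_cross`, `n_restarts`,
#'   `seed`, `ids`.
#' @export
scan_markov_times <- function(graph,
                              t_grid = 10^seq(-2, 2, length.out = 100),
                              n_restarts = 100L, seed = 1L,
                              progress = FALSE) {
  if (!inherits(graph, "learner_graph")) stop("`graph` must be a learner_graph")
  if (any(diff(t_grid) <= 0) || any(t_grid <= 0))
    stop("`t_grid` must be increasing and positive")
  n_restarts <- as.integer(n_restarts)
  if (n_restarts < 1L) stop("`n_restarts` must be >= 1")
  nt <- length(t_grid)
  n <- nrow(graph$adjacency)

  bmats <- lapply(t_grid, function(t) stability_matrix(graph, t))
  best <- vector("list", nt)
  r_star <- numeric(nt)
  ncom <- integer(nt)
  vi_t <- numeric(nt)

  for (k in seq_len(nt)) {
    b <- bmats[[k]]
    bs <- b / max(abs(b))
    ens <- vector("list", n_restarts)
    for (r in seq_len(n_restarts)) {
      rs <- as.integer((as.double(seed) * 69621 + k * 1013 + r) %% 2147483647)
      ens[[r]] <- louvain_dense_impl(bs, rs)
    }
    keys <- vapply(ens, paste, "", collapse = ",")
    uk <- !duplicated(keys)
    uniq <- ens[uk]
    counts <- as.vector(table(factor(keys, levels = keys[uk])))
    # Eq-style stability score: min trace over grid times <= t
    scores <- vapply(uniq, function(lab) {
      min(vapply(seq_len(k), function(kk) trace_block_sum(bmats[[kk]], lab), 0))
    }, 0)
    ibest <- which.max(scores)
    best[[k]] <- uniq[[ibest]]
    r_star[k] <- scores[ibest]
    ncom[k] <- max(uniq[[ibest]])
    vi_t[k] <- vi_ensemble_counted(uniq, counts, n_restarts)
    if (progress && k %% 10L == 0L)
      message(sprintf("scan %d/%d: t = %.3g, c = %d", k, nt, t_grid[k], ncom[k]))
  }

  vi_cross <- matrix(0, nt, nt)
  if (nt > 1L) {
    for (a in seq_len(nt - 1L)) for (b2 in (a + 1L):nt) {
      v <- variation_of_information(best[[a]], best[[b2]])
      vi_cross[a, b2] <- v
      vi_cross[b2, a] <- v
    }
  }
  for (k in seq_len(nt)) names(best[[k]]) <- graph$ids
  structure(list(t_grid = t_grid, best = best, r_star = r_star,
                 n_communities = ncom, vi_t = vi_t, vi_cross = vi_cross,
                 n_restarts = n_restarts, seed = as.integer(seed),
                 ids = graph$ids),
            class = "ms_scan")
}

#' @export
print.ms_scan <- function(x, ...) {
  cat(sprintf("Markov Stability scan: %d times in [%.3g, %.3g], %d restarts\n",
              length(x$t_grid), min(x$t_grid), max(x$t_grid), x$n_restarts))
  cat("communities:", paste(range(x$n_communities), collapse = " .. "), "\n")
  invisible(x)
}

# mean pairwise VI over the ordered pairs of an ensemble given as unique
# partitions with multiplicities (identical pairs contribute 0)
vi_ensemble_counted <- function(uniq, counts, ell) {
  if (ell < 2L || length(uniq) == 1L) return(0)
  tot <- 0
  for (a in seq_along(uniq)) {
    for (b in seq_along(uniq)) {
      if (a == b) next
      tot <- tot + counts[a] * counts[b] *
        variation_of_information(uniq[[a]], uniq[[b]])
    }
  }
  tot / (ell * (ell - 1))
}
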