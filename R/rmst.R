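#' Minimum spanning tree of a distance matrix
#'
#' Deterministic Kruskal construction: candidate edges are ordered
#' lexicographically by (distance, smaller node index, larger node index),
#' so ties are always broken identically. The total weight is the unique
#' MST weight (cross-checked against `igraph::mst` in the test suite).
#'
#' @param dist Symmetric matrix of finite, nonnegative distances.
#' @return Matrix with columns `i`, `j`, `weight`; N-1 rows forming a tree.
#' @export
minimum_spanning_tree <- function(dist) {
  check_dist_matrix(dist)
  n <- nrow(dist)
  if (n < 2L) stop("need at least two nodes")
  pairs <- which(upper.tri(dist), arr.ind = TRUE)
  w <- dist[pairs]
  ord <- order(w, pairs[, 1], pairs[, 2])
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  edges <- matrix(0, nrow = n - 1L, ncol = 3L,
                  dimnames = list(NULL, c("i", "j", "weight")))
  k <- 0L
  for (e in ord) {
    a <- find(pairs[e, 1])
    b <- find(pairs[e, 2])
    if (a != b) {
      parent[a] <- b
      k <- k + 1L
      edges[k, ] <- c(pairs[e, 1], pairs[e, 2], w[e])
      if (k == n - 1L) break
    }
  }
  edges
}

check_dist_matrix <- function(dist) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    stop("`dist` must be a square matrix")
  if (!all(is.finite(dist))) stop("`dist` must be finite")
  if (any(abs(dist - t(dist)) > 1e-8)) stop("`dist` must be symmetric")
  if (any(dist < 0)) stop("`dist` must be nonnegative")
  invisible(TRUE)
}

#' RMST configuration
#'
#' @param gamma Nonnegative relaxation strength; `0` keeps essentially the
#'   MST-explainable edges, larger values admit progressively more edges
#'   (the mask is monotone in `gamma`), and `Inf` yields the complete graph.
#' @param k Neighbour index for the local scale term: `d_i^(k)` is the
#'   distance from node i to its k-th nearest neighbour.
#' @return `rmst_config` object.
#' @export
rmst_config <- function(gamma = 0.5, k = 1L) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma < 0)
    stop("`gamma` must be a single nonnegative number")
  if (!is.finite(k) || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  structure(list(gamma = gamma, k = as.integer(k)), class = "rmst_config")
}

#' Relaxed Minimum Spanning Tree sparsification
#'
#' Keeps edge (i, j) iff
#' \deqn{d_{ij} < \mathrm{mlink}_{ij} + \gamma\,(d_i^{(k)} + d_j^{(k)}),}
#' where `mlink` is the maximum edge weight on the unique MST path between
#' i and j (the bottleneck of the best indirect route) and `d_i^(k)` is the
#' distance from i to its k-th nearest neighbour (a local density scale).
#' All MST edges are always kept, so the mask is connected by construction.
#' Direct similarities that can be explained through chains of stronger
#' similarities are discarded; locally short edges are retained.
#'
#' @param dist Symmetric distance matrix.
#' @param cfg An [rmst_config()].
#' @return Symmetric logical mask (TRUE = edge kept, FALSE on the diagonal).
#' @export
rmst_sparsify <- function(dist, cfg = rmst_config()) {
  check_dist_matrix(dist)
  n <- nrow(dist)
  if (cfg$k >= n) stop("`k` must be smaller than the number of nodes")
  mst <- minimum_spanning_tree(dist)
  mlink <- mst_path_max(mst, n)
  # d_i^(k): k-th smallest off-diagonal distance in row i
  dk <- vapply(seq_len(n), function(i) sort(dist[i, -i])[cfg$k], 0)
  thresh <- mlink + cfg$gamma * outer(dk, dk, `+`)
  mask <- dist < thresh
  mask[cbind(mst[, 1], mst[, 2])] <- TRUE
  mask[cbind(mst[, 2], mst[, 1])] <- TRUE
  diag(mask) <- FALSE
  mask <- mask & t(mask)
  dimnames(mask) <- dimnames(dist)
  mask
}

# max edge weight on the MST path between every pair (N x N, 0 diagonal)
mst_path_max <- function(mst, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(mst))) {
    i <- mst[r, 1]; j <- mst[r, 2]; w <- mst[r, 3]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  out <- matrix(0, n, n)
  for (root in seq_len(n)) {
    seen <- logical(n)
    seen[root] <- TRUE
    stack <- list(c(root, 0))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      node <- top[1]; mx <- top[2]
      nb <- adj[[node]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        if (!seen[v]) {
          seen[v] <- TRUE
          m2 <- max(mx, nb[r, 2])
          out[root, v] <- m2
          stack[[length(stack) + 1L]] <- c(v, m2)
        }
      }
    }
  }
  out
}

#' Build a weighted learner graph from an edge mask and similarities
#'
#' The adjacency is the kernel similarity wherever the mask keeps an edge,
#' zero elsewhere (and on the diagonal). Derived operators are attached:
#' degree vector, combinatorial Laplacian L = D - A, random-walk transition
#' matrix Q = D^-1 A, the stationary measure pi of the chosen dynamics, and
#' a cached spectral decomposition used to evaluate the matrix exponential
#' e^{-tL} at many Markov times cheaply.
#'
#' @param mask Symmetric logical edge mask (e.g. from [rmst_sparsify()]).
#' @param sim Symmetric similarity matrix with unit diagonal.
#' @param pi_mode `"uniform"` pairs the combinatorial Laplacian dynamics
#'   with its uniform stationary measure (default); `"degree"` uses the
#'   random-walk normalised Laplacian with pi proportional to degree.
#' @return `learner_graph` object.
#' @export
build_graph <- function(mask, sim, pi_mode = c("uniform", "degree")) {
  pi_mode <- match.arg(pi_mode)
  if (!is.matrix(mask) || !is.matrix(sim) || !all(dim(mask) == dim(sim)))
    stop("`mask` and `sim` must be square matrices of equal dimension")
  if (any(mask != t(mask))) stop("`mask` must be symmetric")
  a <- sim * (mask * 1)
  diag(a) <- 0
  n <- nrow(a)
  ids <- rownames(sim)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    a > 0, mode = "undirected"))
  if (comp$no != 1L)
    stop("edge mask yields a disconnected graph (", comp$no, " components)")
  deg <- rowSums(a)
  lap <- diag(deg) - a
  q <- a / deg
  if (pi_mode == "uniform") {
    pi <- rep(1 / n, n)
    eig <- eigen(lap, symmetric = TRUE)
    d_sqrt <- NULL
  } else {
    pi <- deg / sum(deg)
    d_sqrt <- sqrt(deg)
    lsym <- lap / outer(d_sqrt, d_sqrt)
    eig <- eigen((lsym + t(lsym)) / 2, symmetric = TRUE)
  }
  structure(list(adjacency = a, ids = ids, degree = deg, laplacian = lap,
                 transition = q, pi = pi, pi_mode = pi_mode,
                 eig = eig, d_sqrt = d_sqrt),
            class = "learner_graph")
}

#' @export
print.learner_graph <- function(x, ...) {
  cat(sprintf("LearnerGraph: %d nodes, %d edges (pi: %s)\n",
              nrow(x$adjacency), sum(x$adjacency > 0) / 2, x$pi_mode))
  invisible(x)
}

#' Matrix exponential of the graph dynamics at Markov time t
#'
#' Evaluates \eqn{e^{-tL}} (uniform mode; L symmetric, via its cached
#' eigendecomposition) or \eqn{e^{-t L_{rw}}} (degree mode, via the
#' symmetric normalised Laplacian similarity transform). Rows sum to 1:
#' each row is the diffusion profile of a walker started at that node.
#'
#' @param graph `learner_graph`.
#' @param t Nonnegative Markov time.
#' @return Dense N x N matrix.
#' @export
graph_propagator <- function(graph, t) {
  if (!is.finite(t) || t < 0) stop("`t` must be nonnegative")
  v <- graph$eig$vectors
  ev <- exp(-t * pmax(graph$eig$values, 0))
  e <- v %*% (ev * t(v))
  if (graph$pi_mode == "degree")
    e <- e * outer(1 / graph$d_sqrt, graph$d_sqrt)
  e
}
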