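#' @keywords internal
#' Cumulative-count observations for one learner
#'
#' A trajectory is represented as cumulative tasks completed versus day:
#' sorting the completion times gives observation pairs (day of k-th
#' completion, k). Optionally thinned to at most `max_obs` evenly spaced
#' points to keep pooled Gaussian-process fits tractable.
#' @noRd
cumulative_obs <- function(series, max_obs = Inf) {
  times <- sort(series_values(series))
  n <- length(times)
  if (n == 0L) stop(empty_series_error())
  idx <- if (is.finite(max_obs) && n > max_obs)
    unique(round(seq(1, n, length.out = max_obs))) else seq_len(n)
  cbind(x = times[idx], y = idx)
}

gp_kernel_matrix <- function(x1, x2, sf, ls) {
  d <- outer(x1, x2, `-`)
  sf^2 * exp(-d^2 / (2 * ls^2))
}

# negative log marginal likelihood of the SE + noise GP (y centred)
gp_neg_logml <- function(theta, x, y) {
  sf <- exp(theta[1]); ls <- exp(theta[2]); sn <- exp(theta[3])
  n <- length(x)
  K <- gp_kernel_matrix(x, x, sf, ls)
  diag(K) <- diag(K) + sn^2 + 1e-8 * sf^2
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
}

#' Fit a Gaussian process to pooled trajectory observations
#'
#' Squared-exponential covariance plus independent observation noise;
#' hyperparameters (signal sd, lengthscale, noise sd) are set by maximising
#' the log marginal likelihood with L-BFGS-B from a small deterministic
#' grid of data-scaled starting points (following the standard
#' Cholesky-based GP regression algorithm). The mean function is the
#' constant sample mean, handled by centring.
#'
#' @param x Observation inputs (days).
#' @param y Observation outputs (cumulative task counts).
#' @param restarts Number of optimisation starts.
#' @param fixed_theta Optional fixed log-hyperparameters `c(log_sf,
#'   log_ls, log_sn)` — skips optimisation (used for fixed-hyperparameter
#'   Bayes-factor comparisons).
#' @return `gp_fit` object: `x`, `y`, `theta`, `log_marginal_likelihood`,
#'   `y_mean`, plus Cholesky factors for prediction.
#' @export
gp_fit <- function(x, y, restarts = 5L, fixed_theta = NULL) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  if (length(x) < 2L)
    stop("need at least two observations to fit a Gaussian process")
  ord <- order(x, y)
  x <- as.numeric(x)[ord]
  y <- as.numeric(y)[ord]
  mu <- mean(y)
  yc <- y - mu
  span <- max(diff(range(x)), 1e-6)
  sdy <- max(stats::sd(y), 1e-6)

  if (is.null(fixed_theta)) {
    ls_grid <- span / c(2, 5, 10, 20, 40)
    starts <- lapply(seq_len(max(1L, as.integer(restarts))), function(i) {
      ls0 <- ls_grid[((i - 1L) %% length(ls_grid)) + 1L]
      log(c(sdy, ls0, sdy * 10^(-1 - (i %% 2))))
    })
    lower <- log(c(sdy * 1e-3, span * 1e-3, sdy * 1e-5))
    upper <- log(c(sdy * 1e3, span * 10, sdy * 10))
    best <- NULL
    for (th0 in starts) {
      fit <- tryCatch(
        stats::optim(th0, gp_neg_logml, x = x, y = yc, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value))
        best <- fit
    }
    if (is.null(best)) stop("GP hyperparameter optimisation failed")
    theta <- best$par
    logml <- -best$value
  } else {
    theta <- fixed_theta
    logml <- -gp_neg_logml(theta, x, yc)
  }

  sf <- exp(theta[1]); ls <- exp(theta[2]); sn <- exp(theta[3])
  K <- gp_kernel_matrix(x, x, sf, ls)
  diag(K) <- diag(K) + sn^2 + 1e-8 * sf^2
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  structure(list(x = x, y = y, y_mean = mu, theta = theta,
                 log_marginal_likelihood = logml,
                 chol = ch, alpha = alpha),
            class = "gp_fit")
}

#' Posterior mean and variance of a fitted Gaussian process
#'
#' @param object `gp_fit`.
#' @param grid Prediction inputs (days).
#' @param ... Unused.
#' @return data.frame with `x`, `mean`, `variance` (pointwise latent
#'   variance, always nonnegative).
#' @export
predict.gp_fit <- function(object, grid, ...) {
  sf <- exp(object$theta[1]); ls <- exp(object$theta[2])
  ks <- gp_kernel_matrix(grid, object$x, sf, ls)
  mean <- object$y_mean + as.vector(ks %*% object$alpha)
  v <- forwardsolve(t(object$chol), t(ks))
  var <- pmax(sf^2 - colSums(v^2), 0)
  data.frame(x = grid, mean = mean, variance = var)
}

#' Gaussian-process mean trajectory of a cluster
#'
#' Pools the cumulative-count observations of all cluster members, fits a
#' Gaussian process ([gp_fit()]), and evaluates the posterior mean and
#' pointwise variance on a day grid. The returned log marginal likelihood
#' is the model evidence of the members' pooled data, the quantity entering
#' Bayes-factor comparisons between cluster-wise and pooled models.
#'
#' @param members List of `event_series` (>= 1).
#' @param grid Day grid for the posterior curves.
#' @param max_obs_per_member Thinning cap per member (evenly spaced).
#' @param restarts,fixed_theta Passed to [gp_fit()].
#' @return List with `curve` (data.frame x, mean, variance),
#'   `log_marginal_likelihood`, `fit`, `n_obs`.
#' @export
gpr_cluster_trajectory <- function(members, grid,
                                   max_obs_per_member = 30L,
                                   restarts = 5L, fixed_theta = NULL) {
  if (length(members) == 0L) stop("`members` must be non-empty")
  obs <- do.call(rbind, lapply(members, cumulative_obs,
                               max_obs = max_obs_per_member))
  if (nrow(obs) < 2L)
    stop("degenerate cluster data: need at least two observations")
  fit <- gp_fit(obs[, "x"], obs[, "y"], restarts = restarts,
                fixed_theta = fixed_theta)
  list(curve = predict(fit, grid),
       log_marginal_likelihood = fit$log_marginal_likelihood,
       fit = fit, n_obs = nrow(obs))
}

#' Bayes factor: cluster-wise versus pooled trajectory models
#'
#' Compares model M1, in which each cluster's trajectories arise from its
#' own Gaussian process, against model M2, a single pooled process for the
#' whole cohort. With equal model priors the Bayes factor reduces to the
#' evidence ratio:
#' \deqn{\log K = \sum_c \log p(D_c \mid M_{1,c}) - \log p(D \mid M_2).}
#' A large positive \eqn{\log K} is evidence that the clusters follow
#' statistically distinct engagement processes. For a single-cluster
#' "partition" \eqn{\log K = 0} exactly.
#'
#' @param cluster_members List of lists of `event_series`, one list per
#'   cluster (non-empty, jointly forming the cohort).
#' @param hyper `"per_cluster"` re-optimises hyperparameters within each
#'   cluster (default); `"pooled"` fixes all models to the pooled fit's
#'   hyperparameters, isolating the effect of the partition itself.
#' @param max_obs_per_member,restarts Passed through to the GP fits.
#' @return `bayes_comparison` object: `K`, `log_K`, `cluster_logml`,
#'   `pooled_logml`, `models`.
#' @export
bayes_factor <- function(cluster_members,
                         hyper = c("per_cluster", "pooled"),
                         max_obs_per_member = 30L, restarts = 5L) {
  hyper <- match.arg(hyper)
  if (length(cluster_members) == 0L) stop("no clusters supplied")
  for (cl in cluster_members)
    if (length(cl) == 0L) stop("empty cluster rejected")
  all_members <- unlist(cluster_members, recursive = FALSE)
  pooled <- gpr_cluster_trajectory(all_members, grid = numeric(0),
                                   max_obs_per_member = max_obs_per_member,
                                   restarts = restarts)
  fixed <- if (hyper == "pooled") pooled$fit$theta else NULL
  cl_logml <- vapply(cluster_members, function(cl) {
    gpr_cluster_trajectory(cl, grid = numeric(0),
                           max_obs_per_member = max_obs_per_member,
                           restarts = restarts,
                           fixed_theta = fixed)$log_marginal_likelihood
  }, 0)
  log_k <- sum(cl_logml) - pooled$log_marginal_likelihood
  structure(list(K = exp(log_k), log_K = log_k,
                 cluster_logml = cl_logml,
                 pooled_logml = pooled$log_marginal_likelihood,
                 models = c(M1 = "independent per-cluster Gaussian processes",
                            M2 = "single pooled Gaussian process"),
                 hyper = hyper),
            class = "bayes_comparison")
}

#' @export
print.bayes_comparison <- function(x, ...) {
  cat(sprintf("Bayes factor K = %.4g (log K = %.3f), %d clusters vs pooled\n",
              x$K, x$log_K, length(x$cluster_logml)))
  invisible(x)
}
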