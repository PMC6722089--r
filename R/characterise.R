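#' Least-squares isotonic regression fit
#'
#' Exact solution of \eqn{\arg\min_x \|y - x\|^2} subject to
#' \eqn{x_1 \le x_2 \le \dots \le x_n}, via pool-adjacent-violators
#' (delegated to [stats::isoreg()]). The fitted vector is piecewise
#' constant; each constant stretch ("block") is the mean of the pooled
#' observations.
#'
#' @param y Finite numeric vector (length >= 1).
#' @return `isotonic_fit` object: `y`, `x` (fitted non-decreasing vector),
#'   `blocks` (data.frame `start`, `end`, `level`).
#' @export
isotonic_fit <- function(y) {
  if (length(y) == 0L) stop("`y` must be non-empty")
  if (!all(is.finite(y))) stop("`y` must be finite")
  x <- if (length(y) == 1L) as.numeric(y) else stats::isoreg(y)$yf
  starts <- c(1L, which(diff(x) > 0) + 1L)
  ends <- c(starts[-1L] - 1L, length(x))
  structure(list(y = as.numeric(y), x = x,
                 blocks = data.frame(start = starts, end = ends,
                                     level = x[starts])),
            class = "isotonic_fit")
}

#' Mean massed-session length of a trajectory
#'
#' Massed ("binge") sessions are plateaux in the task-count-versus-time
#' trajectory: stretches of consecutive tasks completed within a short
#' interval. The completion times (ordered by task index) are first
#' regularised by isotonic regression; maximal runs of consecutive tasks
#' whose fitted times differ by at most `tol_days` form sessions, and the
#' mean session size in tasks is returned (singleton sessions count).
#' A learner completing tasks steadily scores near 1; heavy cramming gives
#' large values.
#'
#' @param series `event_series` or numeric vector of completion times.
#' @param tol_days Tolerance for two consecutive tasks to share a session.
#' @return Mean session length in tasks (>= 1).
#' @export
mean_massed_session_length <- function(series, tol_days = 0) {
  times <- series_values(series)
  if (length(times) == 0L) stop(empty_series_error())
  if (tol_days < 0) stop("`tol_days` must be nonnegative")
  fit <- isotonic_fit(times)$x
  if (length(fit) == 1L) return(1)
  new_session <- diff(fit) > tol_days
  sizes <- rle(cumsum(c(0, new_session)))$lengths
  mean(sizes)
}

#' Fraction of available tasks completed
#'
#' @param series `event_series`.
#' @return Completed / total, in `[0, 1]`.
#' @export
completion_fraction <- function(series) {
  if (!inherits(series, "event_series"))
    stop("`series` must be an event_series")
  if (series$n_total_tasks < 1L) stop("`n_total_tasks` must be >= 1")
  if (length(series$times) > series$n_total_tasks)
    stop("more completions than available tasks")
  length(series$times) / series$n_total_tasks
}

#' Hypergeometric enrichment p-value for a cluster
#'
#' Upper-tail probability \eqn{P(X \ge \mathrm{cluster\_hits})} that a
#' cluster of the given size drawn without replacement from the population
#' contains at least the observed number of labelled members (e.g. low
#' performers). Small values indicate over-representation of the label in
#' the cluster.
#'
#' @param cluster_size Cluster size.
#' @param cluster_hits Labelled members inside the cluster.
#' @param population Cohort size.
#' @param population_hits Labelled members in the whole cohort.
#' @return p-value in (0, 1].
#' @export
enrichment_pvalue <- function(cluster_size, cluster_hits,
                              population, population_hits) {
  args <- c(cluster_size, cluster_hits, population, population_hits)
  if (any(!is.finite(args)) || any(args < 0) || any(args != round(args)))
    stop("all counts must be nonnegative integers")
  if (cluster_size > population || population_hits > population ||
      cluster_hits > cluster_size || cluster_hits > population_hits)
    stop("inconsistent counts: hits must fit inside their sets")
  stats::phyper(cluster_hits - 1, m = population_hits,
                n = population - population_hits,
                k = cluster_size, lower.tail = FALSE)
}

#' Enrichment table across the clusters of a partition
#'
#' One upper-tail hypergeometric test per cluster for over-representation
#' of a binary outcome label (default: low performance). Raw p-values are
#' reported alongside Bonferroni-adjusted ones, since several clusters are
#' tested.
#'
#' @param labels Named cluster assignment (learner_id -> community).
#' @param hits Character vector of learner ids carrying the outcome label.
#' @return data.frame: cluster, size, hits, p_raw, p_bonferroni.
#' @export
cluster_enrichment <- function(labels, hits) {
  lab <- partition_labels(labels)
  if (is.null(names(lab))) stop("`labels` must be named by learner id")
  if (!all(hits %in% names(lab)))
    stop("some `hits` ids are not in the partition")
  pop <- length(lab)
  pop_hits <- length(hits)
  cl <- sort(unique(lab))
  res <- lapply(cl, function(c) {
    members <- names(lab)[lab == c]
    h <- sum(hits %in% members)
    data.frame(cluster = c, size = length(members), hits = h,
               p_raw = enrichment_pvalue(length(members), h, pop, pop_hits))
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out
}

#' Feature-based classifier baseline
#'
#' Trains the two standard classifiers on z-scored per-learner temporal
#' statistics (mean massed-session length and completion fraction): a
#' support vector machine with a radial basis function kernel, and a
#' decision tree limited to depth 4. Reports per-class counts correctly
#' classified on the training set — the comparison surface against the
#' unsupervised clustering.
#'
#' @param features data.frame / matrix of numeric features (rows =
#'   learners).
#' @param labels Factor (or coercible) of performance classes, one per row.
#' @return List with `zscores` (standardised features), `svm_fit`,
#'   `tree_fit`, and `accuracy` (data.frame class, n, svm_correct,
#'   tree_correct).
#' @export
baseline_classify <- function(features, labels) {
  x <- as.matrix(features)
  if (!is.numeric(x)) stop("`features` must be numeric")
  y <- factor(labels)
  if (nrow(x) != length(y)) stop("`features` rows and `labels` differ")
  if (nlevels(y) < 2L) stop("need at least two classes")
  z <- scale(x)
  z[is.nan(z)] <- 0  # constant feature columns
  df <- data.frame(z)
  df$.class <- y

  svm_fit <- e1071::svm(.class ~ ., data = df, kernel = "radial")
  tree_fit <- rpart::rpart(.class ~ ., data = df, method = "class",
                           control = rpart::rpart.control(
                             maxdepth = 4, minsplit = 2, minbucket = 1,
                             cp = 0, xval = 0))
  pred_svm <- stats::predict(svm_fit, df)
  pred_tree <- stats::predict(tree_fit, df, type = "class")
  acc <- do.call(rbind, lapply(levels(y), function(cl) {
    in_cl <- y == cl
    data.frame(class = cl, n = sum(in_cl),
               svm_correct = sum(pred_svm[in_cl] == cl),
               tree_correct = sum(pred_tree[in_cl] == cl))
  }))
  list(zscores = z, svm_fit = svm_fit, tree_fit = tree_fit, accuracy = acc)
}

#' Per-cluster statistical profile
#'
#' Convenience wrapper computing, for each cluster of a partition, the mean
#' massed-session length and the mean completion fraction of its members.
#'
#' @param series_list Named list of `event_series` (ids must cover the
#'   partition).
#' @param labels Named cluster assignment.
#' @param tol_days Session tolerance passed to
#'   [mean_massed_session_length()].
#' @return data.frame: cluster, size, mean_massed_session_length,
#'   mean_completion_fraction.
#' @export
cluster_profiles <- function(series_list, labels, tol_days = 0) {
  lab <- partition_labels(labels)
  if (is.null(names(lab))) stop("`labels` must be named by learner id")
  if (!all(names(lab) %in% names(series_list)))
    stop("series missing for some labelled learners")
  do.call(rbind, lapply(sort(unique(lab)), function(c) {
    ids <- names(lab)[lab == c]
    msl <- vapply(series_list[ids], mean_massed_session_length, 0,
                  tol_days = tol_days)
    cf <- vapply(series_list[ids], completion_fraction, 0)
    data.frame(cluster = c, size = length(ids),
               mean_massed_session_length = mean(msl),
               mean_completion_fraction = mean(cf))
  }))
}
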