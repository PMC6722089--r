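#' Select robust partitions from a Markov Stability scan
#'
#' A partition is considered robust when it is (i) persistent across
#' scales — optimal over a contiguous stretch of Markov time with a
#' constant number of communities and a low-VI(t, t') diagonal block — and
#' (ii) consistent under the optimisation — exhibiting a low value (dip) of
#' the restart-ensemble VI(t) within that stretch. Candidates are the
#' maximal runs of constant c(t) whose mean cross-time VI falls below
#' `theta_plateau` and whose length is at least `l_min` grid points; within
#' each run the partition at the t minimising the (window-3 smoothed) VI(t)
#' is returned. Candidates are ranked by plateau length, then dip depth.
#'
#' An empty candidate list (with a warning) signals a lack of natural
#' cluster structure at the chosen thresholds; the raw VI curves remain
#' available in the scan for manual inspection.
#'
#' @param scan An `ms_scan` from [scan_markov_times()].
#' @param theta_plateau Upper bound on the mean VI(t, t') within a block.
#' @param l_min Minimum plateau length in grid points.
#' @return `robust_report` object: list with `candidates` (each holding
#'   `t_window`, `t_star`, `labels`, `n_communities`, `plateau_length`,
#'   `vi_dip_depth`, `block_mean_vi`), the thresholds used, and
#'   `containment` scores between consecutive candidates (coarse vs fine),
#'   reporting how closely the partitions nest.
#' @export
select_robust_partitions <- function(scan, theta_plateau = 0.1, l_min = 5L) {
  if (!inherits(scan, "ms_scan")) stop("`scan` must be an ms_scan")
  nt <- length(scan$t_grid)
  l_min <- max(1L, as.integer(l_min))

  vi_smooth <- smooth_window3(scan$vi_t)
  runs <- constant_runs(scan$n_communities)
  candidates <- list()
  for (r in runs) {
    len <- r[2] - r[1] + 1L
    if (len < l_min) next
    idx <- r[1]:r[2]
    block <- scan$vi_cross[idx, idx, drop = FALSE]
    off <- block[upper.tri(block)]
    block_mean <- if (length(off)) mean(off) else 0
    if (block_mean > theta_plateau) next
    k_star <- idx[which.min(vi_smooth[idx])]
    dip <- max(vi_smooth[idx]) - min(vi_smooth[idx])
    candidates[[length(candidates) + 1L]] <- list(
      t_window = c(scan$t_grid[r[1]], scan$t_grid[r[2]]),
      t_star = scan$t_grid[k_star],
      labels = scan$best[[k_star]],
      n_communities = scan$n_communities[k_star],
      plateau_length = len,
      vi_dip_depth = dip,
      block_mean_vi = block_mean)
  }
  if (length(candidates) == 0L) {
    warning("no robust partition found at the given thresholds; ",
            "the data may lack natural cluster structure")
  } else {
    ord <- order(-vapply(candidates, function(c) c$plateau_length, 0L),
                 -vapply(candidates, function(c) c$vi_dip_depth, 0))
    candidates <- candidates[ord]
  }
  containment <- NULL
  if (length(candidates) >= 2L) {
    byc <- candidates[order(vapply(candidates, function(c) c$n_communities, 0L),
                            decreasing = TRUE)]
    containment <- vapply(seq_len(length(byc) - 1L), function(i)
      containment_score(byc[[i]]$labels, byc[[i + 1L]]$labels), 0)
  }
  structure(list(candidates = candidates,
                 theta_plateau = theta_plateau, l_min = l_min,
                 containment = containment),
            class = "robust_report")
}

#' @export
print.robust_report <- function(x, ...) {
  if (length(x$candidates) == 0L) {
    cat("No robust partitions at theta =", x$theta_plateau, "\n")
    return(invisible(x))
  }
  cat(sprintf("%d robust partition(s):\n", length(x$candidates)))
  for (c in x$candidates) {
    cat(sprintf("  c = %d over t in [%.3g, %.3g] (len %d), t* = %.3g, dip %.3g\n",
                c$n_communities, c$t_window[1], c$t_window[2],
                c$plateau_length, c$t_star, c$vi_dip_depth))
  }
  invisible(x)
}

smooth_window3 <- function(v) {
  n <- length(v)
  if (n < 3L) return(v)
  out <- v
  out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  out
}

constant_runs <- function(x) {
  n <- length(x)
  starts <- c(1L, which(diff(x) != 0) + 1L)
  ends <- c(starts[-1L] - 1L, n)
  Map(c, starts, ends)
}

#' Containment score between a fine and a coarse partition
#'
#' Fraction of nodes whose fine community maps entirely-by-majority into a
#' single coarse community: \eqn{\sum_c \max_{c'} |C_c \cap C'_{c'}| / N}.
#' 1 means the fine partition nests exactly inside the coarse one (a
#' perfect hierarchy); values near 1 indicate a quasi-hierarchy.
#'
#' @param fine,coarse Label vectors over the same nodes.
#' @return Score in (0, 1].
#' @export
containment_score <- function(fine, coarse) {
  fine <- partition_labels(fine)
  coarse <- partition_labels(coarse)
  tab <- table(fine, coarse)
  sum(apply(tab, 1, max)) / length(fine)
}
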