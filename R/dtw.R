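#' Dynamic time warping distance between two event series
#'
#' Cumulative cost of the optimal monotone warping path from cell (1, 1) to
#' (n, m) of the alignment grid, with squared-difference local cost
#' \eqn{(x_i - y_j)^2} and the symmetric step set
#' \{(i-1, j), (i, j-1), (i-1, j-1)\}. No warping window and no slope
#' weighting are applied, so series of different lengths (e.g. learners who
#' skipped different tasks) are aligned natively. The distance is symmetric,
#' nonnegative, and zero iff the two series are elementwise equal.
#'
#' @param x,y `event_series` objects or plain numeric vectors.
#' @return Nonnegative DTW distance.
#' @examples
#' dtw_distance(c(1, 2, 3), c(2, 3))  # 1
#' @export
dtw_distance <- function(x, y) {
  xv <- series_values(x)
  yv <- series_values(y)
  if (length(xv) == 0L || length(yv) == 0L)
    stop(empty_series_error())
  if (!all(is.finite(xv)) || !all(is.finite(yv)))
    stop("series values must be finite")
  dtw_distance_impl(xv, yv)
}

series_values <- function(x) {
  if (inherits(x, "event_series")) x$times else as.numeric(x)
}

empty_series_error <- function() {
  structure(class = c("tempoclust_empty_series", "error", "condition"),
            list(message = "cannot compute DTW distance of an empty series",
                 call = sys.call(-1)))
}

#' Gaussian DTW kernel
#'
#' Maps a DTW distance to a similarity in (0, 1] via
#' \eqn{k = \exp(-D / \sigma^2)}, strictly decreasing in the distance and
#' equal to 1 at distance 0 (self-similarity).
#'
#' @param dist Nonnegative DTW distance(s).
#' @param sigma Positive kernel bandwidth \eqn{\sigma}.
#' @return Similarity value(s) in (0, 1].
#' @export
dtw_kernel <- function(dist, sigma) {
  if (!all(is.finite(dist))) stop("`dist` must be finite")
  if (any(dist < 0)) stop("`dist` must be nonnegative")
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number")
  exp(-dist / sigma^2)
}

#' Kernel configuration for the similarity matrix
#'
#' @param sigma_rule `"median_distance"` sets \eqn{\sigma^2} to the median
#'   off-diagonal DTW distance (scale-free default, invariant to the choice
#'   of time unit); `"fixed"` uses the supplied `sigma`.
#' @param sigma Fixed bandwidth, required when `sigma_rule = "fixed"`.
#' @return `kernel_config` object.
#' @export
kernel_config <- function(sigma_rule = c("median_distance", "fixed"),
                          sigma = NULL) {
  sigma_rule <- match.arg(sigma_rule)
  if (sigma_rule == "fixed") {
    if (is.null(sigma) || !is.finite(sigma) || sigma <= 0)
      stop("fixed `sigma` must be a positive number")
  }
  structure(list(sigma_rule = sigma_rule, sigma = sigma),
            class = "kernel_config")
}

#' Pairwise DTW distances and kernel similarities for a cohort
#'
#' Computes all N(N-1)/2 DTW distances once (mirrored into a symmetric
#' matrix) and kernelises them into a similarity matrix with unit diagonal.
#' Under the default `median_distance` rule the bandwidth is set to
#' \eqn{\sigma^2 = } median of the off-diagonal distances before
#' kernelisation.
#'
#' @param cohort List of `event_series` (all ids distinct) or of numeric
#'   vectors (named).
#' @param cfg A [kernel_config()].
#' @return List with `dist` (DTW distance matrix), `sim` (similarity
#'   matrix, entries in (0, 1], unit diagonal), and `sigma` (the bandwidth
#'   actually used). Matrices carry learner ids as dimnames.
#' @export
pairwise_similarity <- function(cohort, cfg = kernel_config()) {
  if (length(cohort) < 2L) stop("need at least two series")
  ids <- vapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    if (inherits(s, "event_series")) s$learner_id
    else if (!is.null(names(cohort))) names(cohort)[i]
    else as.character(i)
  }, "")
  if (anyDuplicated(ids)) stop("duplicate learner ids in cohort")
  values <- lapply(cohort, series_values)
  lens <- lengths(values)
  if (any(lens == 0L)) {
    stop("empty series for learner(s): ",
         paste(ids[lens == 0L], collapse = ", "),
         " (drop them or use missing = \"impute\")")
  }
  D <- dtw_pairwise_impl(values)
  dimnames(D) <- list(ids, ids)
  sigma <- if (cfg$sigma_rule == "median_distance") {
    med <- stats::median(D[upper.tri(D)])
    if (med <= 0) stop("median off-diagonal distance is zero; use a fixed sigma")
    sqrt(med)
  } else {
    cfg$sigma
  }
  A <- dtw_kernel(D, sigma)
  diag(A) <- 1
  dimnames(A) <- dimnames(D)
  list(dist = D, sim = A, sigma = sigma)
}
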