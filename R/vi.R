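#' Normalised variation of information between two partitions
#'
#' Information-theoretic distance
#' \deqn{VI(H, H') = \frac{2\,\Omega(H, H') - \Omega(H) - \Omega(H')}
#'                        {\log N} \in [0, 1],}
#' where \eqn{\Omega} are Shannon entropies of the community relative
#' frequencies (and of the joint contingency table). VI is a true metric on
#' partitions: symmetric, satisfies the triangle inequality, and is 0 iff
#' the two partitions are identical up to relabelling. The log N
#' normalisation makes 1 the distance between the all-singletons and the
#' one-block partition.
#'
#' @param p1,p2 Community label vectors of equal length N >= 2 (or
#'   `partition` objects).
#' @return VI in `[0, 1]`.
#' @export
variation_of_information <- function(p1, p2) {
  l1 <- partition_labels(p1)
  l2 <- partition_labels(p2)
  n <- length(l1)
  if (length(l2) != n) stop("partitions must cover the same elements")
  if (n < 2L) stop("VI is undefined for N = 1 (log N = 0)")
  joint <- table(l1, l2) / n
  h1 <- shannon(rowSums(joint))
  h2 <- shannon(colSums(joint))
  h12 <- shannon(as.vector(joint))
  v <- (2 * h12 - h1 - h2) / log(n)
  min(max(v, 0), 1)
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mean pairwise variation of information of a partition ensemble
#'
#' \eqn{VI(t) = \frac{1}{\ell(\ell-1)} \sum_{i \ne j} VI(H_i, H_j)} over
#' the ordered pairs of an ensemble of \eqn{\ell} partitions; 0 when all
#' are identical (and for \eqn{\ell = 1}, where the pair sum is empty).
#'
#' @param partitions List of label vectors or `partition` objects.
#' @return Mean pairwise VI.
#' @export
vi_ensemble <- function(partitions) {
  ell <- length(partitions)
  if (ell < 2L) return(0)
  labs <- lapply(partitions, partition_labels)
  tot <- 0
  for (a in seq_len(ell - 1L)) {
    for (b in (a + 1L):ell) {
      tot <- tot + 2 * variation_of_information(labs[[a]], labs[[b]])
    }
  }
  tot / (ell * (ell - 1))
}
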