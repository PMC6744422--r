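#' Jensen-Shannon divergence between two probability vectors
#'
#' JSD(p, q) = KL(p || m)/2 + KL(q || m)/2 with m = (p + q)/2, natural
#' logarithm, and the convention 0 * log 0 = 0. The divergence is symmetric,
#' non-negative and bounded by log(2); its square root is a metric.
#'
#' @param p,q Non-negative numeric vectors of equal length, each summing to
#'   1 (within `tol`).
#' @param tol Tolerance on the sum-to-one check.
#' @return The divergence, a value in `[0, log(2)]`.
#' @examples
#' jsd(c(0.5, 0.5), c(0.5, 0.5))  # 0
#' jsd(c(1, 0), c(0, 1))          # log(2)
#' @export
jsd <- function(p, q, tol = 1e-9) {
  if (length(p) != length(q))
    stop("'p' and 'q' must have the same length")
  if (any(p < 0) || any(q < 0))
    stop("probability vectors must be non-negative")
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol)
    stop("'p' and 'q' must each sum to 1")
  m <- (p + q) / 2
  0.5 * .kl(p, m) + 0.5 * .kl(q, m)
}

# KL(p || m); safe because m >= p/2, so m = 0 only where p = 0
.kl <- function(p, m) {
  i <- p > 0
  sum(p[i] * (log(p[i]) - log(m[i])))
}

#' Pairwise Jensen-Shannon distance matrix of a mutation profile set
#'
#' Each eligible sample's weight vector (binary calls or VAFs) is
#' normalized to a probability distribution over variants; entry (i, j) is
#' the Jensen-Shannon divergence between samples i and j (or its square
#' root when `use_sqrt = TRUE`, which makes the entries a metric). Normal
#' samples and samples flagged as low-purity are excluded, as are samples
#' whose weight vector is all zero (with a warning).
#'
#' @param mp A [mutation_profile_set()].
#' @param use_sqrt Return the square root of the divergence.
#' @return A symmetric, zero-diagonal numeric matrix with sample ids as
#'   dimnames, of class `"dist_jsd"` (a plain matrix).
#' @export
pairwise_distances <- function(mp, use_sqrt = FALSE) {
  stopifnot(inherits(mp, "mutation_profile_set"))
  ids <- .eligible_samples(mp)
  w <- mp$weights[, ids, drop = FALSE]
  sums <- colSums(w)
  if (any(sums == 0)) {
    warning("excluding all-zero sample(s): ",
            paste(ids[sums == 0], collapse = ", "))
    ids <- ids[sums > 0]
    w <- w[, ids, drop = FALSE]
    sums <- sums[sums > 0]
  }
  if (length(ids) < 3L)
    stop("fewer than 3 usable samples; cannot build a distance matrix")
  pr <- sweep(w, 2, sums, "/")
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- jsd(pr[, i], pr[, j])
      d[i, j] <- d[j, i] <- if (use_sqrt) sqrt(v) else v
    }
  }
  d
}
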