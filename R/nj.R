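#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion and branch-length
#' formulas, producing an unrooted tree. The implementation is fully
#' deterministic: taxa are sorted lexicographically before agglomeration and
#' ties in the Q-criterion are broken by the lowest (row, column) index
#' pair. Negative branch lengths, which arise for non-additive input, are
#' retained (downstream classification reads only the topology and the
#' distance matrix, never branch lengths) but reported via a message.
#'
#' For an additive distance matrix, path lengths on the returned tree
#' reproduce the input distances exactly (up to floating-point error).
#'
#' @param d Symmetric, zero-diagonal, finite numeric matrix with at least
#'   three labelled taxa (dimnames required), e.g. from
#'   [pairwise_distances()].
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' nj_tree(d)
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("'d' must have taxon labels as dimnames")
  if (nrow(d) != ncol(d) || any(!is.finite(d)) ||
      max(abs(d - t(d))) > 1e-12 || any(abs(diag(d)) > 1e-12))
    stop("'d' must be a finite symmetric matrix with zero diagonal")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")

  ord <- order(rownames(d), method = "radix")
  d <- d[ord, ord, drop = FALSE]
  # each active cluster is carried as a newick fragment
  nwk <- rownames(d)
  neg <- FALSE

  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest (row, col) pair among the minima, col-major scan transposed to
    # give row-major priority
    idx <- which(t(q) == min(q), arr.ind = TRUE)[1L, ]
    i <- idx[2L]; j <- idx[1L]
    if (i > j) { k <- i; i <- j; j <- k }
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    if (bi < 0 || bj < 0) neg <- TRUE
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    new_nwk <- sprintf("(%s:%.12g,%s:%.12g)", nwk[i], bi, nwk[j], bj)
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]), c(dn[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    lab <- c(rownames(q)[keep], paste0("{", rownames(q)[i], "}"))
    dimnames(d) <- list(lab, lab)
  }

  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (min(b1, b2, b3) < 0) neg <- TRUE
  if (neg) message("nj_tree: negative branch length(s) retained")
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nwk[1], b1, nwk[2], b2, nwk[3], b3)
  ape::read.tree(text = txt)
}
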