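#' EASE score: jackknifed one-sided Fisher exact p-value
#'
#' The Expression Analysis Systematic Explorer score is a conservative
#' gene-set enrichment p-value: the one-sided (upper-tail) Fisher exact
#' test on the 2x2 gene-list x term contingency table after decrementing
#' the overlap cell by one (floored at zero). With an overlap of 0 or 1 the
#' score is therefore 1, penalizing categories supported by a single gene.
#'
#' @param overlap Genes shared between the list and the term.
#' @param list_size Size of the gene list.
#' @param term_size Number of background genes annotated to the term.
#' @param background Size of the annotated background universe.
#' @return The EASE p-value, in `(0, 1]`.
#' @examples
#' ease_score(5, 100, 15, 1000)
#' @export
ease_score <- function(overlap, list_size, term_size, background) {
  if (overlap < 0 || list_size < 0 || term_size < 0 || background < 1)
    stop("counts must be non-negative (background >= 1)")
  if (overlap > min(list_size, term_size) ||
      list_size > background || term_size > background ||
      background - term_size - list_size + overlap < 0)
    stop("inconsistent contingency counts")
  a <- max(overlap - 1L, 0L)
  tab <- matrix(c(a, list_size - overlap,
                  term_size - overlap,
                  background - term_size - list_size + overlap), 2L)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' EASE-score enrichment of a gene list over a gene-set collection
#'
#' Scores every term of a GMT-style gene-set collection against a gene
#' list with [ease_score()], using a user-supplied background universe.
#' Terms at `p < alpha` (default 0.01) are flagged significant.
#'
#' @param genes Character vector of gene ids (the list).
#' @param gene_sets Named list of character vectors (term id -> member
#'   genes), e.g. from [read_gmt()].
#' @param background Character vector of background gene ids, or a single
#'   integer giving the background size (then terms and list are assumed
#'   fully contained in it).
#' @param alpha Significance cutoff on the EASE p-value.
#' @return Data frame with columns `term`, `overlap`, `list_size`,
#'   `term_size`, `background`, `ease_p`, `significant`, ordered by
#'   `ease_p`.
#' @export
ease_enrichment <- function(genes, gene_sets, background, alpha = 0.01) {
  genes <- unique(genes)
  if (is.character(background)) {
    universe <- unique(background)
    genes <- intersect(genes, universe)
    gene_sets <- lapply(gene_sets, intersect, universe)
    n_bg <- length(universe)
  } else {
    n_bg <- as.integer(background)
    gene_sets <- lapply(gene_sets, unique)
  }
  res <- data.frame(
    term = names(gene_sets),
    overlap = vapply(gene_sets, function(s) length(intersect(genes, s)),
                     integer(1)),
    list_size = length(genes),
    term_size = lengths(gene_sets),
    background = n_bg,
    stringsAsFactors = FALSE
  )
  res$ease_p <- mapply(ease_score, res$overlap, res$list_size,
                       res$term_size, res$background)
  res$significant <- res$ease_p < alpha
  res <- res[order(res$ease_p, res$term), ]
  rownames(res) <- NULL
  res
}
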