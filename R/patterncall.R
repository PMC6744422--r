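#' Scale the second plate to the first by cumulative expression
#'
#' Between-plate intensity differences are removed by multiplying every
#' expression value on plate 2 by the ratio of the plates' cumulative
#' (summed over the shared gene set) expression, so that after scaling the
#' two plates have equal totals. Plate 1 is left untouched.
#'
#' @param study An [expression_study()] spanning two plates.
#' @return The study with plate 2 rescaled.
#' @export
scale_plates <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  plates <- sort(unique(study$samples$plate))
  if (length(plates) == 1L) return(study)
  if (length(plates) != 2L) stop("expected exactly two plates")
  p1 <- study$samples$plate == plates[1]
  p2 <- study$samples$plate == plates[2]
  t1 <- sum(study$expression[, p1])
  t2 <- sum(study$expression[, p2])
  if (t1 == 0 || t2 == 0) stop("plate with zero cumulative expression")
  study$expression[, p2] <- study$expression[, p2] * (t1 / t2)
  study
}

#' Keep only annotated protein-coding genes
#'
#' Retains genes carrying an associated gene symbol (`symbol_present`) and
#' annotated as protein-coding; the number removed is reported.
#'
#' @param study An [expression_study()] with annotation flags.
#' @return The filtered study.
#' @export
filter_annotated <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  keep <- study$genes$symbol_present & study$genes$protein_coding
  n_drop <- sum(!keep)
  if (n_drop) message("filter_annotated: removed ", n_drop, " gene(s)")
  if (!any(keep)) warning("no genes left after annotation filter")
  study$expression <- study$expression[keep, , drop = FALSE]
  study$genes <- study$genes[keep, , drop = FALSE]
  rownames(study$genes) <- NULL
  study
}

#' Differential-expression call of one sample triplet against the baselines
#'
#' A gene is flagged for a triplet when all three criteria hold:
#' (i) the triplet's mean is at least `fold_up` times (up) or at most
#' `fold_down` times (down) the mean over the pooled baseline replicates;
#' (ii) the gene's range (max - min) across the submatrix of the baselines
#' plus that triplet is at or above the `range_pct` percentile of all
#' genes' ranges in that submatrix (linear interpolation; ties retained);
#' (iii) every sample of the triplet sits on the same side of every
#' baseline replicate (consistent polarity).
#'
#' @param study An [expression_study()].
#' @param triplet_group A `replicate_group` id of an experimental triplet.
#' @param fold_up,fold_down Fold-change cutoffs for up / down calls.
#' @param range_pct Percentile (0-100) for the range criterion.
#' @return Character vector per gene: `"up"`, `"down"` or `"none"`.
#' @export
de_vs_baseline <- function(study, triplet_group, fold_up = 1.5,
                           fold_down = 0.5, range_pct = 25) {
  stopifnot(inherits(study, "expression_study"))
  trip <- study$samples$sample_id[study$samples$replicate_group == triplet_group &
                                    !study$samples$is_baseline]
  base <- .baseline_samples(study)
  if (length(trip) != 3L)
    stop("replicate group '", triplet_group, "' is not an experimental triplet")
  if (!length(base)) stop("study has no baseline replicates")
  x_t <- study$expression[, trip, drop = FALSE]
  x_b <- study$expression[, base, drop = FALSE]
  m_t <- rowMeans(x_t)
  m_b <- rowMeans(x_b)

  sub <- cbind(x_b, x_t)
  rng <- apply(sub, 1L, function(v) max(v) - min(v))
  rng_ok <- rng >= stats::quantile(rng, range_pct / 100)

  above <- apply(x_t, 1L, min) > apply(x_b, 1L, max)   # all 3 x |base| pairs >
  below <- apply(x_t, 1L, max) < apply(x_b, 1L, min)

  out <- rep("none", nrow(sub))
  out[m_t >= fold_up * m_b & rng_ok & above] <- "up"
  out[m_t <= fold_down * m_b & rng_ok & below] <- "down"
  stats::setNames(out, rownames(study$expression))
}

#' Exact p-value of complete rank separation between two groups
#'
#' Under exchangeability, the probability that all `n1` values of one group
#' rank above (one fixed direction) all `n2` values of the other is
#' `1 / choose(n1 + n2, n1)`. This is the per-gene p-value attached to
#' every gene flagged by a complete-separation comparison; with the default
#' 6/9/9 design the three tissue comparisons give 1.9980e-04, 1.9980e-04
#' and 2.0568e-05.
#'
#' @param n1,n2 Group sizes (>= 1).
#' @return The one-direction separation probability, in `(0, 1]`.
#' @examples
#' separation_pvalue(6, 9)  # 1.998e-04
#' separation_pvalue(9, 9)  # 2.0568e-05
#' @export
separation_pvalue <- function(n1, n2) {
  if (n1 < 1L || n2 < 1L) stop("group sizes must be >= 1")
  1 / choose(n1 + n2, n1)
}

#' Complete-separation comparison between two sample types
#'
#' For every gene, compares all samples of `type_a` with all samples of
#' `type_b`: if every `type_b` value exceeds every `type_a` value the gene
#' is flagged `"up"` (B above A); if every `type_b` value is below every
#' `type_a` value, `"down"`; otherwise `"none"`. Each flagged gene carries
#' the comparison's exact rank-separation p-value
#' `1 / choose(n1 + n2, n1)`.
#'
#' @param study An [expression_study()] (plate-scaled).
#' @param type_a,type_b Sample-type labels, e.g. `"MFP"` and `"AxLN"`.
#' @return An object of class `"comparison_result"`: list with
#'   `comparison`, `type_a`, `type_b`, `n1`, `n2`, `direction` (named
#'   per-gene vector), and `p` (the constant per-flagged-gene p-value).
#' @export
pairwise_type_comparison <- function(study, type_a, type_b) {
  stopifnot(inherits(study, "expression_study"))
  a <- .type_samples(study, type_a)
  b <- .type_samples(study, type_b)
  if (!length(a) || !length(b))
    stop("sample type absent from study: ",
         if (!length(a)) type_a else type_b)
  if (length(a) < 2L || length(b) < 2L)
    warning("sample type with fewer than 2 samples; p-value is weak")
  xa <- study$expression[, a, drop = FALSE]
  xb <- study$expression[, b, drop = FALSE]
  max_a <- do.call(pmax, as.data.frame(xa))
  min_a <- do.call(pmin, as.data.frame(xa))
  max_b <- do.call(pmax, as.data.frame(xb))
  min_b <- do.call(pmin, as.data.frame(xb))
  dir <- rep("none", nrow(xa))
  dir[min_b > max_a] <- "up"
  dir[max_b < min_a] <- "down"
  structure(
    list(
      comparison = paste0(type_a, "_vs_", type_b),
      type_a = type_a, type_b = type_b,
      n1 = length(a), n2 = length(b),
      direction = stats::setNames(dir, rownames(study$expression)),
      p = separation_pvalue(length(a), length(b))
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>", x$comparison, sprintf("(n=%d vs %d)", x$n1, x$n2),
      "\n  flagged:", sum(x$direction != "none"), "genes, per-gene p =",
      format(x$p, digits = 5), "\n")
  invisible(x)
}

#' Merge pairwise comparisons and assign six-way plasticity patterns
#'
#' Genes flagged in at least two of the three pairwise tissue comparisons
#' are retained (the merged heat map). Each retained gene is then tagged
#' per sample type: the type with the highest mean expression is `Up`, the
#' lowest is `Down`, and the intermediate type inherits the tag of
#' whichever extreme type is nearest under
#' `d(X, Y) = min_{i,j} |x_i - y_j|` over the two types' samples. The tag
#' triple over (MFP, AxLN, AxLN-LuM) -- or whatever three types the study
#' carries -- is one of six patterns: a `Up-Up-Down`, b `Down-Down-Up`,
#' c `Up-Down-Down`, d `Down-Up-Up`, e `Up-Down-Up`, f `Down-Up-Down`;
#' a/b, c/d and e/f are pattern/anti-pattern couples, and e/f (the
#' AxLN-divergent couple) mark genes reversibly regulated specifically in
#' the LN. Genes with tied type means are excluded (reported via message).
#'
#' The per-gene p-value is the product of the separation p-values of the
#' comparisons that flagged the gene (the joint probability of the observed
#' separations under exchangeability); Benjamini-Hochberg q-values over the
#' retained genes are reported alongside.
#'
#' @param study A plate-scaled [expression_study()].
#' @param comparisons List of three `"comparison_result"` objects computed
#'   on the same gene universe.
#' @param types The ordered sample-type triple defining the tag order;
#'   defaults to `c("MFP", "AxLN", "AxLN_LuM")`.
#' @return A data frame of class `"pattern_table"`: columns `gene`, one tag
#'   column per type, `pattern`, `divergent_type`, the per-comparison
#'   directions, `p` and `q`.
#' @export
merge_and_assign_patterns <- function(study, comparisons,
                                      types = c("MFP", "AxLN", "AxLN_LuM")) {
  stopifnot(inherits(study, "expression_study"), length(comparisons) == 3L)
  genes <- rownames(study$expression)
  flags <- vapply(comparisons, function(cr) {
    if (!setequal(names(cr$direction), genes))
      stop("comparisons must share the study's gene universe")
    cr$direction[genes] != "none"
  }, logical(length(genes)))
  flags <- matrix(flags, nrow = length(genes))
  retained <- genes[rowSums(flags) >= 2L]
  type_cols <- lapply(types, function(tp) .type_samples(study, tp))
  names(type_cols) <- types
  if (any(!lengths(type_cols))) stop("missing sample type(s) in study")

  tag_mat <- matrix(NA_character_, length(retained), 3L,
                    dimnames = list(retained, types))
  dropped <- character(0)
  for (g in retained) {
    vals <- lapply(type_cols, function(cols) study$expression[g, cols])
    means <- vapply(vals, mean, numeric(1))
    if (anyDuplicated(means)) { dropped <- c(dropped, g); next }
    hi <- types[which.max(means)]
    lo <- types[which.min(means)]
    mid <- setdiff(types, c(hi, lo))
    d_hi <- min(abs(outer(vals[[mid]], vals[[hi]], "-")))
    d_lo <- min(abs(outer(vals[[mid]], vals[[lo]], "-")))
    tags <- stats::setNames(character(3), types)
    tags[hi] <- "Up"; tags[lo] <- "Down"
    tags[mid] <- if (d_hi <= d_lo) "Up" else "Down"
    tag_mat[g, ] <- tags[types]
  }
  if (length(dropped)) {
    message("excluding ", length(dropped), " gene(s) with tied type means")
    tag_mat <- tag_mat[setdiff(retained, dropped), , drop = FALSE]
    retained <- setdiff(retained, dropped)
  }

  if (!length(retained)) {
    out <- data.frame(gene = character(0), stringsAsFactors = FALSE)
    for (tp in types) out[[paste0("tag_", tp)]] <- character(0)
    out$pattern <- character(0)
    out$divergent_type <- character(0)
    for (cr in comparisons) out[[paste0("dir_", cr$comparison)]] <- character(0)
    out$p <- numeric(0)
    out$q <- numeric(0)
    class(out) <- c("pattern_table", "data.frame")
    return(out)
  }

  pat_defs <- .pattern_tags()
  pat_key <- vapply(pat_defs, paste, "", collapse = "-")
  tag_str <- apply(tag_mat, 1L, paste, collapse = "-")
  pattern <- names(pat_key)[match(tag_str, pat_key)]
  # divergent type: the one whose tag differs from the other two
  divergent <- vapply(seq_along(retained), function(i) {
    tg <- tag_mat[i, ]
    maj <- names(sort(table(tg), decreasing = TRUE))[1]
    types[tg != maj][1]
  }, character(1))

  p <- vapply(seq_along(retained), function(i) {
    g <- retained[i]
    prod(vapply(comparisons,
                function(cr) if (cr$direction[g] != "none") cr$p else 1,
                numeric(1)))
  }, numeric(1))

  out <- data.frame(gene = retained, stringsAsFactors = FALSE)
  for (tp in types) out[[paste0("tag_", tp)]] <- tag_mat[, tp]
  out$pattern <- pattern
  out$divergent_type <- divergent
  for (cr in comparisons)
    out[[paste0("dir_", cr$comparison)]] <- unname(cr$direction[retained])
  out$p <- p
  out$q <- stats::p.adjust(p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("pattern_table", "data.frame")
  out
}

#' Cluster a pattern/anti-pattern submatrix and split it at the sign change
#'
#' Takes the genes of one pattern/anti-pattern couple (a/b, c/d or e/f),
#' log2-transforms and row-mean-centers their expression over the
#' experimental samples, orders the rows by hierarchical clustering
#' (average linkage on 1 - Pearson row correlation), and splits the heat
#' map into its top and bottom halves at the point where the divergent
#' sample type's centered values change sign. Half membership is
#' equivalently the sign of the divergent type's centered mean: positive
#' (divergent type Up) genes form the `"top"` half, negative the
#' `"bottom"`; clustering only orders rows and cannot change membership.
#'
#' @param study A plate-scaled [expression_study()].
#' @param pattern_table A `"pattern_table"` from
#'   [merge_and_assign_patterns()].
#' @param pattern_pair Two pattern letters forming a couple, e.g.
#'   `c("e", "f")`.
#' @return Data frame with columns `gene`, `pattern`, `half` and `order`
#'   (row position in the clustered heat map, top half first); the centered
#'   matrix is attached as attribute `"centered"`.
#' @export
cluster_and_split <- function(study, pattern_table,
                              pattern_pair = c("e", "f")) {
  stopifnot(inherits(study, "expression_study"),
            inherits(pattern_table, "pattern_table"))
  rows <- pattern_table[pattern_table$pattern %in% pattern_pair, ]
  if (!nrow(rows)) stop("no genes in pattern(s) ",
                        paste(pattern_pair, collapse = "/"))
  div_types <- unique(rows$divergent_type)
  if (length(div_types) != 1L)
    stop("patterns ", paste(pattern_pair, collapse = "/"),
         " do not share a divergent sample type")
  exp_cols <- study$samples$sample_id[!study$samples$is_baseline]
  x <- log2(study$expression[rows$gene, exp_cols, drop = FALSE])
  x <- x - rowMeans(x)
  div_cols <- .type_samples(study, div_types)
  div_mean <- rowMeans(x[, div_cols, drop = FALSE])
  half <- ifelse(div_mean > 0, "top", "bottom")

  ord <- if (nrow(x) >= 3L) {
    cors <- suppressWarnings(stats::cor(t(x)))
    cors[!is.finite(cors)] <- 0
    stats::hclust(stats::as.dist(1 - cors), method = "average")$order
  } else seq_len(nrow(x))
  # top half first, clustering order within each half
  ord <- c(ord[half[ord] == "top"], ord[half[ord] == "bottom"])

  out <- data.frame(
    gene = rows$gene[ord], pattern = rows$pattern[ord], half = half[ord],
    order = seq_along(ord), stringsAsFactors = FALSE
  )
  attr(out, "centered") <- x[ord, , drop = FALSE]
  out
}

#' Full plasticity-pattern calling pipeline
#'
#' Convenience wrapper: plate scaling, annotation filter, the three
#' pairwise tissue comparisons, and pattern assignment.
#'
#' @inheritParams merge_and_assign_patterns
#' @param study An [expression_study()].
#' @return A `"pattern_table"`; the scaled, filtered study and the three
#'   comparison results are attached as attributes `"study"` and
#'   `"comparisons"`.
#' @export
call_patterns <- function(study, types = c("MFP", "AxLN", "AxLN_LuM")) {
  study <- filter_annotated(scale_plates(study))
  comparisons <- list(
    pairwise_type_comparison(study, types[1], types[2]),
    pairwise_type_comparison(study, types[1], types[3]),
    pairwise_type_comparison(study, types[2], types[3])
  )
  pt <- merge_and_assign_patterns(study, comparisons, types = types)
  attr(pt, "study") <- study
  attr(pt, "comparisons") <- comparisons
  pt
}
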