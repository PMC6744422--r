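#' Root a tree at the primary tumor sample
#'
#' Re-roots an unrooted sample tree at the designated primary sample, the
#' convention used when reading seeding relationships off the phylogeny.
#' When several primary samples are present the one nearest the rest of the
#' tumor (smallest mean distance to all non-primary samples in `d`) is
#' chosen; ties are broken by lexicographic sample id. Rooting re-orients
#' the tree only: the leaf set and all pairwise path lengths are unchanged.
#'
#' @param tree Unrooted `ape::phylo` tree over the sample ids.
#' @param mp The [mutation_profile_set()] the tree was built from (supplies
#'   sample roles).
#' @param d Optional distance matrix used for the multi-primary tie-break;
#'   defaults to [pairwise_distances()] of `mp`.
#' @return A rooted `ape::phylo` tree.
#' @export
root_at_primary <- function(tree, mp, d = NULL) {
  roles <- sample_roles(mp)[tree$tip.label]
  if (anyNA(roles)) stop("tree has leaves without role annotation")
  primaries <- tree$tip.label[roles == "primary"]
  if (!length(primaries))
    stop("no primary sample among the leaves; cannot root")
  root_tip <- .choose_primary(primaries, tree$tip.label, d, mp)
  ape::root(tree, outgroup = root_tip, resolve.root = TRUE)
}

.choose_primary <- function(primaries, labels, d, mp) {
  primaries <- sort(primaries, method = "radix")
  if (length(primaries) == 1L) return(primaries)
  if (is.null(d)) d <- pairwise_distances(mp)
  others <- setdiff(labels, primaries)
  if (!length(others)) return(primaries[1L])
  mean_d <- vapply(primaries, function(p) mean(d[p, others]), numeric(1))
  chosen <- primaries[which.min(mean_d)]  # which.min keeps first = lexicographic
  message("multiple primary samples; rooting at ", chosen)
  chosen
}

#' Classify a patient's seeding mode from a rooted tree
#'
#' Scans every clade (the full descendant leaf set of each internal node)
#' of the rooted sample tree. A patient is called `"LN_met_mediated"` iff
#' some clade contains at least one distant metastasis and at least one
#' lymph-node sample and no primary sample -- i.e. a distant metastasis
#' shares a more recent common ancestor with a LN metastasis than with the
#' primary tumor. Otherwise the call is `"LN_met_independent"`.
#'
#' @param rooted A rooted `ape::phylo` tree whose leaves are tumor samples.
#' @param roles Named character vector mapping each leaf to `"primary"`,
#'   `"lymph_node"` or `"distant"` (normal samples must not appear).
#' @return `"LN_met_mediated"` or `"LN_met_independent"`.
#' @export
classify_seeding <- function(rooted, roles) {
  stopifnot(inherits(rooted, "phylo"))
  if (is.null(rooted$edge)) stop("malformed tree")
  tip_roles <- roles[rooted$tip.label]
  if (anyNA(tip_roles))
    stop("missing role for leaf/leaves: ",
         paste(rooted$tip.label[is.na(tip_roles)], collapse = ", "))
  if (any(tip_roles == "normal"))
    stop("normal samples must be excluded before classification")
  for (clade in .clades(rooted)) {
    r <- tip_roles[clade]
    if (any(r == "distant") && any(r == "lymph_node") && !any(r == "primary"))
      return("LN_met_mediated")
  }
  "LN_met_independent"
}

# descendant tip-label sets of all internal nodes, by edge-list accumulation
.clades <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  desc <- c(as.list(seq_len(ntip)), vector("list", nnode))
  # postorder: children resolved before parents
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1L]; ch <- edges[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(desc[(ntip + 1L):(ntip + nnode)],
         function(i) tree$tip.label[sort(unique(i))])
}

#' Lymph-node and distant-metastasis distance ratios
#'
#' `ln_distance_ratio()` returns, for each LN sample, D_LM / D_LP: the
#' shortest distance from the LN to any distant metastasis over the
#' distance from the LN to the (nearest) primary sample. A ratio below 1
#' means the LN is phylogenetically closer to a distant metastasis than to
#' the primary. `met_distance_ratio()` returns, for each distant
#' metastasis, D_ML / D_MP: its shortest distance to any LN sample over its
#' distance to the (nearest) primary; a ratio below 1 marks a metastasis
#' closer to the LN lineage than to the primary.
#'
#' Ratios with a zero denominator are undefined and returned as `NA` with a
#' warning; callers should exclude them from summaries.
#'
#' @param d Symmetric distance matrix over tumor samples, e.g. from
#'   [pairwise_distances()].
#' @param roles Named character vector of sample roles.
#' @return Named numeric vector, one ratio per LN (resp. distant) sample.
#' @export
ln_distance_ratio <- function(d, roles) {
  .distance_ratio(d, roles, from = "lymph_node", to = "distant")
}

#' @rdname ln_distance_ratio
#' @export
met_distance_ratio <- function(d, roles) {
  .distance_ratio(d, roles, from = "distant", to = "lymph_node")
}

.distance_ratio <- function(d, roles, from, to) {
  roles <- roles[rownames(d)]
  grp <- function(r) rownames(d)[!is.na(roles) & roles == r]
  from_ids <- grp(from); to_ids <- grp(to); prim <- grp("primary")
  if (!length(from_ids) || !length(to_ids) || !length(prim))
    stop("need at least one primary, one lymph_node and one distant sample")
  out <- vapply(from_ids, function(s) {
    num <- min(d[s, to_ids])
    den <- min(d[s, prim])
    if (den == 0) return(NA_real_)
    num / den
  }, numeric(1))
  if (anyNA(out))
    warning("undefined ratio (zero distance to primary) for: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

# One full classification pass: distances -> NJ -> rooting -> clade rule.
# Internal; works on a raw weight matrix so bootstrap replicates (which
# contain duplicated variant rows) can reuse it.
.classify_once <- function(weights, roles, use_sqrt = FALSE, quiet = FALSE) {
  run <- function() {
    sums <- colSums(weights)
    keep <- sums > 0
    if (!quiet && any(!keep))
      warning("excluding all-zero sample(s): ",
              paste(colnames(weights)[!keep], collapse = ", "))
    w <- weights[, keep, drop = FALSE]
    if (ncol(w) < 3L) stop("fewer than 3 usable samples")
    pr <- sweep(w, 2, sums[keep], "/")
    ids <- colnames(w)
    n <- length(ids)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      v <- jsd(pr[, i], pr[, j])
      d[i, j] <- d[j, i] <- if (use_sqrt) sqrt(v) else v
    }
    tree <- nj_tree(d)
    prim <- ids[roles[ids] == "primary"]
    if (!length(prim)) stop("no primary sample")
    root_tip <- if (length(prim) == 1L) prim else {
      others <- setdiff(ids, prim)
      prim <- sort(prim, method = "radix")
      prim[which.min(vapply(prim, function(p) mean(d[p, others]), numeric(1)))]
    }
    rooted <- ape::root(tree, outgroup = root_tip, resolve.root = TRUE)
    list(classification = classify_seeding(rooted, roles), d = d,
         tree = tree, rooted = rooted)
  }
  if (quiet) suppressWarnings(suppressMessages(run())) else run()
}

#' Seeding classification with bootstrap confidence
#'
#' Runs the full per-patient pipeline -- Jensen-Shannon distance matrix,
#' neighbor-joining tree, rooting at the primary, clade rule -- on the
#' complete mutation data, then assesses robustness by resampling the
#' variants (matrix rows) with replacement to the original count `n_iter`
#' times and repeating the pipeline on each replicate. The confidence score
#' is 100 times the fraction of replicates whose classification matches the
#' full-data call. Replicates in which a sample drops out (all-zero weight
#' vector) proceed without that sample; replicates on which classification
#' is impossible count as non-matches.
#'
#' @param mp A [mutation_profile_set()] with at least one primary, one
#'   lymph-node and one distant sample.
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param seed Integer seed making the resampling reproducible.
#' @param use_sqrt Use the square root of the divergence as the distance.
#' @param resample_fraction If non-`NULL`, draw `floor(fraction * n)`
#'   variants *without* replacement instead of the default bootstrap, for
#'   sensitivity analysis.
#' @return An object of class `"seeding_call"`: list with `patient_id`,
#'   `classification`, `ln_ratios`, `met_ratios`, `confidence` (in
#'   `[0, 100]`), `n_bootstrap`, `seed`, and the point-estimate `tree`,
#'   `rooted` tree and distance matrix `d`.
#' @export
bootstrap_confidence <- function(mp, n_iter = 1000L, seed = NULL,
                                 use_sqrt = FALSE, resample_fraction = NULL) {
  stopifnot(inherits(mp, "mutation_profile_set"), n_iter >= 1L)
  roles <- sample_roles(mp)
  ids <- .eligible_samples(mp)
  w <- mp$weights[, ids, drop = FALSE]
  full <- .classify_once(w, roles, use_sqrt = use_sqrt)

  if (!is.null(seed)) set.seed(seed)
  nv <- nrow(w)
  n_draw <- if (is.null(resample_fraction)) nv else {
    stopifnot(resample_fraction > 0, resample_fraction <= 1)
    max(1L, floor(resample_fraction * nv))
  }
  replace <- is.null(resample_fraction)
  matches <- 0L
  failed <- 0L
  for (b in seq_len(n_iter)) {
    idx <- sample.int(nv, n_draw, replace = replace)
    cls <- tryCatch(
      .classify_once(w[idx, , drop = FALSE], roles,
                     use_sqrt = use_sqrt, quiet = TRUE)$classification,
      error = function(e) NA_character_
    )
    if (is.na(cls)) failed <- failed + 1L
    else if (cls == full$classification) matches <- matches + 1L
  }
  if (failed)
    message(failed, " bootstrap iteration(s) could not be classified ",
            "(counted as non-matches)")

  structure(
    list(
      patient_id = mp$patient_id,
      classification = full$classification,
      ln_ratios = ln_distance_ratio(full$d, roles),
      met_ratios = met_distance_ratio(full$d, roles),
      confidence = 100 * matches / n_iter,
      n_bootstrap = as.integer(n_iter),
      seed = seed,
      tree = full$tree,
      rooted = full$rooted,
      d = full$d
    ),
    class = "seeding_call"
  )
}

#' Classify a patient without bootstrapping
#'
#' Point-estimate version of [bootstrap_confidence()]: one pass of the
#' distance/tree/clade pipeline, no confidence score.
#'
#' @inheritParams bootstrap_confidence
#' @return A `"seeding_call"` with `confidence = NA` and `n_bootstrap = 0`.
#' @export
classify_patient <- function(mp, use_sqrt = FALSE) {
  roles <- sample_roles(mp)
  ids <- .eligible_samples(mp)
  full <- .classify_once(mp$weights[, ids, drop = FALSE], roles,
                         use_sqrt = use_sqrt)
  structure(
    list(
      patient_id = mp$patient_id,
      classification = full$classification,
      ln_ratios = ln_distance_ratio(full$d, roles),
      met_ratios = met_distance_ratio(full$d, roles),
      confidence = NA_real_,
      n_bootstrap = 0L,
      seed = NULL,
      tree = full$tree,
      rooted = full$rooted,
      d = full$d
    ),
    class = "seeding_call"
  )
}

#' @export
print.seeding_call <- function(x, ...) {
  cat("<seeding_call> patient", x$patient_id, "->", x$classification, "\n")
  if (!is.na(x$confidence))
    cat("  bootstrap confidence:", x$confidence, "/ 100 (",
        x$n_bootstrap, "iterations )\n")
  cat("  LN ratios (D_LM/D_LP): ",
      paste(sprintf("%s=%.3g", names(x$ln_ratios), x$ln_ratios),
            collapse = ", "), "\n")
  cat("  met ratios (D_ML/D_MP):",
      paste(sprintf("%s=%.3g", names(x$met_ratios), x$met_ratios),
            collapse = ", "), "\n")
  invisible(x)
}
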