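#' Mutation profile set
#'
#' Container for one patient's somatic-mutation profiles: a variants x
#' samples matrix of non-negative weights (binary presence calls or variant
#' allele fractions) together with the role of each sample in the metastatic
#' cascade. Variants are stored in lexicographic order of their identifiers,
#' so downstream resampling is invariant to the order in which variants were
#' supplied.
#'
#' @param patient_id Single string identifying the patient.
#' @param weights Numeric matrix, variants x samples, entries >= 0. Row
#'   names are variant identifiers (must be unique), column names sample
#'   identifiers.
#' @param roles Character vector, one of `"primary"`, `"lymph_node"`,
#'   `"distant"`, `"normal"` per sample (named by sample id, or in column
#'   order of `weights`).
#' @param site_label Optional character vector of anatomical site labels.
#' @param purity_ok Logical vector; samples flagged `FALSE` (low tumor
#'   purity) are excluded from distance computation. Default all `TRUE`.
#'
#' @return An object of class `"mutation_profile_set"`: a list with
#'   elements `patient_id`, `weights`, and `samples` (a data frame with
#'   columns `sample_id`, `role`, `site_label`, `purity_ok`).
#' @export
mutation_profile_set <- function(patient_id, weights, roles,
                                 site_label = NULL, purity_ok = NULL) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  weights <- as.matrix(weights)
  if (is.null(rownames(weights)) || is.null(colnames(weights)))
    stop("'weights' must have variant row names and sample column names")
  if (anyDuplicated(rownames(weights)))
    stop("duplicate variant ids in 'weights'")
  if (anyDuplicated(colnames(weights)))
    stop("duplicate sample ids in 'weights'")
  if (!is.numeric(weights) || any(!is.finite(weights)) || any(weights < 0))
    stop("'weights' must be finite, non-negative and numeric")

  sample_ids <- colnames(weights)
  roles <- .match_per_sample(roles, sample_ids, "roles")
  bad <- setdiff(unique(roles), c("primary", "lymph_node", "distant", "normal"))
  if (length(bad))
    stop("unknown sample role(s): ", paste(bad, collapse = ", "))
  if (is.null(site_label)) site_label <- sample_ids
  site_label <- .match_per_sample(site_label, sample_ids, "site_label")
  if (is.null(purity_ok)) purity_ok <- rep(TRUE, length(sample_ids))
  purity_ok <- as.logical(.match_per_sample(purity_ok, sample_ids, "purity_ok"))

  # canonical variant order: lexicographic by id (C collation)
  ord <- order(rownames(weights), method = "radix")
  weights <- weights[ord, , drop = FALSE]

  structure(
    list(
      patient_id = patient_id,
      weights = weights,
      samples = data.frame(
        sample_id = sample_ids, role = roles,
        site_label = site_label, purity_ok = purity_ok,
        stringsAsFactors = FALSE
      )
    ),
    class = "mutation_profile_set"
  )
}

.match_per_sample <- function(x, sample_ids, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(sample_ids, names(x))
    if (length(missing))
      stop("'", what, "' missing entries for sample(s): ",
           paste(missing, collapse = ", "))
    x <- x[sample_ids]
  }
  if (length(x) != length(sample_ids))
    stop("'", what, "' must have one entry per sample")
  unname(x)
}

#' @export
print.mutation_profile_set <- function(x, ...) {
  cat("<mutation_profile_set> patient", x$patient_id, "\n")
  cat(" ", nrow(x$weights), "variants x", ncol(x$weights), "samples\n")
  print(table(x$samples$role))
  invisible(x)
}

# samples eligible for the distance matrix: tumor samples passing purity
.eligible_samples <- function(mp) {
  keep <- mp$samples$role != "normal" & mp$samples$purity_ok
  mp$samples$sample_id[keep]
}

# role lookup keyed by sample id
sample_roles <- function(mp) {
  stats::setNames(mp$samples$role, mp$samples$sample_id)
}
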