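#' Simulate one patient's mutation profiles under a known seeding topology
#'
#' Builds a clone tree for the requested seeding mode, drops a
#' Poisson(`lambda_mut`) number of somatic mutations on every branch, and
#' gives each sample the union of mutations accumulated along its clone's
#' path from the (normal) root. Under `"ln_mediated"` seeding the distant
#' clones descend from a lymph-node clone, so every distant sample inherits
#' the LN branch's private mutations; under `"ln_independent"` they branch
#' off the tumor's common ancestor directly and share no LN-private
#' mutations.
#'
#' Call noise is then applied to the tumor samples: each true presence is
#' dropped with probability `fn_rate` (false negative), and false-positive
#' calls are planted with probability `fp_rate` per sample into a global
#' pool of never-true variant ids, so the variant universe (and hence
#' bootstrap resampling) stays well defined. The matched normal sample is
#' kept noise-free and all-zero; it carries the truth and is excluded from
#' distance computation anyway.
#'
#' Optionally the binary calls can be degraded to pseudo variant-allele
#' fractions by drawing Beta(20 * call + 1, 20 * (1 - call) + 1).
#'
#' @param seeding_mode `"ln_mediated"` or `"ln_independent"`.
#' @param n_primary,n_ln,n_distant Number of primary / lymph-node / distant
#'   samples (each >= 1).
#' @param lambda_mut Poisson mean number of mutations per branch (> 0).
#' @param fn_rate,fp_rate False-negative / false-positive call rates, in
#'   `[0, 1)`.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param patient_id Identifier for the simulated patient.
#' @param vaf Emit pseudo-VAF weights instead of binary calls.
#' @return A list with `profile` (a [mutation_profile_set()]) and `truth`
#'   (class `"sim_truth"`: the seeding mode, the clone tree as an edge
#'   table, and all simulation parameters).
#' @export
simulate_patient <- function(seeding_mode = c("ln_mediated", "ln_independent"),
                             n_primary = 1L, n_ln = 1L, n_distant = 2L,
                             lambda_mut = 20, fn_rate = 0, fp_rate = 0,
                             seed = NULL, patient_id = "SIM", vaf = FALSE) {
  seeding_mode <- match.arg(seeding_mode)
  if (n_primary < 1L || n_ln < 1L || n_distant < 1L)
    stop("sample counts must all be >= 1")
  if (lambda_mut <= 0) stop("'lambda_mut' must be > 0")
  if (fn_rate < 0 || fn_rate >= 1 || fp_rate < 0 || fp_rate >= 1)
    stop("'fn_rate' and 'fp_rate' must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  tree <- .build_clone_tree(seeding_mode, n_primary, n_ln, n_distant)
  tree$mutation_count <- stats::rpois(nrow(tree), lambda_mut)
  n_true <- sum(tree$mutation_count)
  if (n_true == 0L) stop("no mutations drawn; increase 'lambda_mut'")
  variant_ids <- sprintf("v%05d", seq_len(n_true))
  # mutations carried by each branch, in tree (edge) order
  branch_vars <- split(variant_ids,
                       rep(seq_len(nrow(tree)), tree$mutation_count))

  # path from root to each clone, as edge indices
  parent_of <- stats::setNames(tree$parent, tree$child)
  path_edges <- function(clone) {
    idx <- integer(0)
    while (clone != "normal") {
      e <- which(tree$child == clone)
      idx <- c(e, idx)
      clone <- parent_of[[clone]]
    }
    idx
  }

  sample_clones <- tree$child[tree$role != "internal"]
  roles <- stats::setNames(tree$role[tree$role != "internal"], sample_clones)
  sample_ids <- c(sample_clones, "N1")
  roles <- c(roles, N1 = "normal")

  # global false-positive pool: never-true variant ids
  n_pool <- if (fp_rate > 0) max(10L, ceiling(0.1 * n_true)) else 0L
  pool_ids <- if (n_pool) sprintf("fp%05d", seq_len(n_pool)) else character(0)
  all_ids <- c(variant_ids, pool_ids)

  w <- matrix(0, length(all_ids), length(sample_ids),
              dimnames = list(all_ids, sample_ids))
  for (s in sample_clones) {
    vars <- unlist(branch_vars[as.character(path_edges(s))], use.names = FALSE)
    calls <- rep(0, length(all_ids))
    calls[match(vars, all_ids)] <- 1
    if (fn_rate > 0) {
      on <- which(calls == 1)
      calls[on[stats::runif(length(on)) < fn_rate]] <- 0
    }
    if (fp_rate > 0 && n_pool) {
      pool_idx <- n_true + seq_len(n_pool)
      calls[pool_idx[stats::runif(n_pool) < fp_rate]] <- 1
    }
    w[, s] <- calls
  }
  if (vaf)
    w[] <- stats::rbeta(length(w), 20 * w + 1, 20 * (1 - w) + 1)

  profile <- mutation_profile_set(patient_id, w, roles)
  truth <- structure(
    list(
      seeding_mode = seeding_mode,
      clone_tree = tree,
      params = list(n_primary = n_primary, n_ln = n_ln,
                    n_distant = n_distant, lambda_mut = lambda_mut,
                    fn_rate = fn_rate, fp_rate = fp_rate, seed = seed,
                    vaf = vaf)
    ),
    class = "sim_truth"
  )
  list(profile = profile, truth = truth)
}

# Clone tree as an edge table (one Poisson(lambda) mutation branch per row).
#
# Shared structure: normal -> MRCA (trunk); the primary samples hang off a
# common primary-lineage clone (P_anc, created when there are >= 2 of
# them); the first LN clone L1 is a child of the MRCA and further LN
# clones descend from it.
#
# ln_mediated: every distant clone is a child of L1, so distant samples
# inherit the LN branch's private mutations and cluster with the LN.
#
# ln_independent: each distant clone descends from a primary subclone
# (round-robin over the primaries), i.e. distant mets are seeded
# hematogenously from the primary tumor; distant samples then share a
# mutation branch with a primary sample, never with the LN.
.build_clone_tree <- function(seeding_mode, n_primary, n_ln, n_distant) {
  prim <- sprintf("T%d", seq_len(n_primary))
  lns <- sprintf("L%d", seq_len(n_ln))
  mets <- sprintf("D%d", seq_len(n_distant))
  edges <- data.frame(parent = "normal", child = "MRCA", role = "internal",
                      stringsAsFactors = FALSE)
  add <- function(parent, child, role) {
    edges <<- rbind(edges, data.frame(parent = parent, child = child,
                                      role = role, stringsAsFactors = FALSE))
  }
  p_root <- if (n_primary > 1L) { add("MRCA", "P_anc", "internal"); "P_anc" }
            else "MRCA"
  add("MRCA", lns[1], "lymph_node")
  if (n_ln > 1L) add(lns[1], lns[-1], "lymph_node")
  if (seeding_mode == "ln_mediated") {
    add(p_root, prim, "primary")
    add(lns[1], mets, "distant")
  } else {
    # primary subclones seeding distant mets; T_i sister to its mets
    host <- prim[((seq_len(n_distant) - 1L) %% n_primary) + 1L]
    for (i in seq_len(n_primary)) {
      if (prim[i] %in% host) {
        sub <- paste0("C", i)
        add(p_root, sub, "internal")
        add(sub, prim[i], "primary")
        add(sub, mets[host == prim[i]], "distant")
      } else {
        add(p_root, prim[i], "primary")
      }
    }
  }
  edges$mutation_count <- NA_integer_
  edges
}

#' Simulate a patient cohort with a fixed fraction of LN-mediated seeding
#'
#' Simulates `n_patients` independent patients; exactly
#' `round(n_patients * fraction_ln_mediated)` of them are assigned the
#' `"ln_mediated"` truth (deterministic rounding), the rest
#' `"ln_independent"`, in an order shuffled under the seed. All patients
#' share the remaining simulation parameters.
#'
#' The default is two primary samples per patient: with a single primary
#' leaf the clade rule is degenerate, because after rooting at that leaf
#' its sibling clade contains every LN and distant sample and no primary,
#' so every patient would be called LN-met mediated. A second primary
#' sample makes the classification informative.
#'
#' @param n_patients Number of patients (>= 1).
#' @param fraction_ln_mediated Target fraction of LN-mediated patients, in
#'   `[0, 1]`.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @inheritParams simulate_patient
#' @return A list with `patients` (list of [mutation_profile_set()]) and
#'   `truth` (class `"sim_truth"`; `seeding_mode` is the per-patient label
#'   vector).
#' @export
simulate_cohort <- function(n_patients, fraction_ln_mediated,
                            n_primary = 2L, n_ln = 1L, n_distant = 2L,
                            lambda_mut = 20, fn_rate = 0, fp_rate = 0,
                            seed = NULL, vaf = FALSE) {
  if (n_patients < 1L) stop("'n_patients' must be >= 1")
  if (fraction_ln_mediated < 0 || fraction_ln_mediated > 1)
    stop("'fraction_ln_mediated' must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n_med <- as.integer(round(n_patients * fraction_ln_mediated))
  modes <- sample(c(rep("ln_mediated", n_med),
                    rep("ln_independent", n_patients - n_med)))
  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    patients[[i]] <- simulate_patient(
      modes[i], n_primary = n_primary, n_ln = n_ln, n_distant = n_distant,
      lambda_mut = lambda_mut, fn_rate = fn_rate, fp_rate = fp_rate,
      seed = NULL, patient_id = sprintf("SIM%03d", i), vaf = vaf
    )$profile
  }
  truth <- structure(
    list(
      seeding_mode = stats::setNames(
        modes, vapply(patients, `[[`, "", "patient_id")),
      params = list(n_patients = n_patients,
                    fraction_ln_mediated = fraction_ln_mediated,
                    n_primary = n_primary, n_ln = n_ln,
                    n_distant = n_distant, lambda_mut = lambda_mut,
                    fn_rate = fn_rate, fp_rate = fp_rate, seed = seed,
                    vaf = vaf)
    ),
    class = "sim_truth"
  )
  list(patients = patients, truth = truth)
}
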