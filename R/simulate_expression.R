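#' Default two-plate array design
#'
#' The replicate design the simulator (and the pattern caller's defaults)
#' assume: two baseline cell lines, each a quadruplicate; experimental
#' triplicates totalling 6 MFP, 9 AxLN and 9 AxLN-LuM samples; everything
#' split over two hybridization plates, with one baseline quadruplicate on
#' each plate so cross-plate scaling can be checked against a common
#' reference. The 32 arrays are balanced 16/16 across the plates: scaling
#' plates to equal cumulative expression is only unbiased when the plates
#' carry the same number of arrays.
#'
#' @return Data frame with columns `sample_id`, `plate`, `sample_type`,
#'   `replicate_group`, `is_baseline`.
#' @export
default_array_design <- function() {
  grp <- function(type, group, n, plate, baseline = FALSE) {
    data.frame(
      sample_id = sprintf("%s_r%d", group, seq_len(n)),
      plate = plate, sample_type = type, replicate_group = group,
      is_baseline = baseline, stringsAsFactors = FALSE
    )
  }
  rbind(
    grp("baseline_GFP", "GFP", 4L, 1L, TRUE),
    grp("MFP", "MFP_t1", 3L, 1L), grp("MFP", "MFP_t2", 3L, 1L),
    grp("AxLN", "AxLN_t1", 3L, 1L), grp("AxLN", "AxLN_t2", 3L, 1L),
    grp("baseline_mCh", "mCh", 4L, 2L, TRUE),
    grp("AxLN", "AxLN_t3", 3L, 2L),
    grp("AxLN_LuM", "LuM_t1", 3L, 2L), grp("AxLN_LuM", "LuM_t2", 3L, 2L),
    grp("AxLN_LuM", "LuM_t3", 3L, 2L)
  )
}

# the six plasticity patterns: Up/Down tags over (MFP, AxLN, AxLN_LuM)
.pattern_tags <- function() {
  list(
    a = c(MFP = "Up",   AxLN = "Up",   AxLN_LuM = "Down"),
    b = c(MFP = "Down", AxLN = "Down", AxLN_LuM = "Up"),
    c = c(MFP = "Up",   AxLN = "Down", AxLN_LuM = "Down"),
    d = c(MFP = "Down", AxLN = "Up",   AxLN_LuM = "Up"),
    e = c(MFP = "Up",   AxLN = "Down", AxLN_LuM = "Up"),
    f = c(MFP = "Down", AxLN = "Up",   AxLN_LuM = "Down")
  )
}

#' Simulate a two-plate expression study with planted plasticity patterns
#'
#' Null genes fluctuate around a gene-specific baseline level with
#' multiplicative lognormal noise (arrays are ratio-scale, so noise is
#' multiplicative and positivity is preserved). Planted genes additionally
#' have every sample of an "Up"-tagged sample type multiplied by `fold`,
#' while "Down"-tagged types and the baselines stay at the gene's baseline
#' level; e.g. pattern f (Down-Up-Down) at `fold = 2` puts the AxLN samples
#' at exactly twice the level of everything else when `noise_sd = 0`.
#' Finally every sample on plate 2 is multiplied by `plate_scale`,
#' emulating a between-plate intensity difference that [scale_plates()]
#' must undo.
#'
#' @param n_null Number of unregulated (null) genes.
#' @param n_per_pattern Number of genes planted per pattern (6 patterns).
#' @param fold Fold effect applied to Up-tagged sample types (> 1).
#' @param noise_sd Standard deviation of the lognormal noise on the log
#'   scale (>= 0).
#' @param plate_scale Multiplicative intensity factor applied to plate 2.
#' @param design Replicate design data frame; defaults to
#'   [default_array_design()].
#' @param baseline_mean_log Mean (log scale) of the per-gene baseline
#'   levels, drawn lognormal(baseline_mean_log, 0.5).
#' @param seed Integer seed; identical seeds give bit-identical studies.
#' @return List with `study` (an [expression_study()]) and `truth` (class
#'   `"sim_truth"`: `planted_pattern`, a per-gene vector with levels
#'   `"a"`..`"f"` or `NA` for null genes, plus all parameters).
#' @export
simulate_expression_study <- function(n_null = 1000L, n_per_pattern = 0L,
                                      fold = 2, noise_sd = 0.05,
                                      plate_scale = 1,
                                      design = default_array_design(),
                                      baseline_mean_log = log(100),
                                      seed = NULL) {
  if (fold <= 1) stop("'fold' must be > 1")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (plate_scale <= 0) stop("'plate_scale' must be > 0")
  req <- c("sample_id", "plate", "sample_type", "replicate_group",
           "is_baseline")
  if (!all(req %in% names(design)) || nrow(design) == 0L ||
      !any(design$is_baseline) || all(design$is_baseline))
    stop("degenerate design: need baseline and experimental sample groups")
  if (!is.null(seed)) set.seed(seed)

  patterns <- .pattern_tags()
  planted <- rep(names(patterns), each = n_per_pattern)
  n_genes <- n_null + length(planted)
  if (n_genes < 1L) stop("no genes requested")
  gene_ids <- sprintf("g%06d", seq_len(n_genes))
  pattern_of <- stats::setNames(
    c(rep(NA_character_, n_null), planted), gene_ids)

  base_level <- stats::rlnorm(n_genes, baseline_mean_log, 0.5)
  n_samp <- nrow(design)
  # multiplicative effect per gene x sample: fold for Up-tagged types
  eff <- matrix(1, n_genes, n_samp)
  if (length(planted)) {
    for (p in names(patterns)) {
      rows <- which(!is.na(pattern_of) & pattern_of == p)
      up_types <- names(patterns[[p]])[patterns[[p]] == "Up"]
      cols <- which(design$sample_type %in% up_types)
      eff[rows, cols] <- fold
    }
  }
  noise <- if (noise_sd > 0)
    matrix(exp(stats::rnorm(n_genes * n_samp, 0, noise_sd)), n_genes, n_samp)
  else 1
  expr <- base_level * eff * noise
  expr[, design$plate == 2L] <- expr[, design$plate == 2L] * plate_scale
  dimnames(expr) <- list(gene_ids, design$sample_id)

  study <- expression_study(expr, design)
  truth <- structure(
    list(
      planted_pattern = pattern_of,
      params = list(n_null = n_null, n_per_pattern = n_per_pattern,
                    fold = fold, noise_sd = noise_sd,
                    plate_scale = plate_scale, seed = seed,
                    baseline_mean_log = baseline_mean_log)
    ),
    class = "sim_truth"
  )
  list(study = study, truth = truth)
}
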