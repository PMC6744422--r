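test_that("scale_plates equalizes cumulative totals and fixes a 2x plate", {
  sim <- simulate_expression_study(n_null = 40, noise_sd = 0.05,
                                   plate_scale = 2, seed = 21)
  st <- scale_plates(sim$study)
  p1 <- st$samples$plate == 1
  expect_equal(sum(st$expression[, p1]), sum(st$expression[, !p1]),
               tolerance = 1e-9)
  # noiseless 2x plate: scaling must exactly halve it
  sim2 <- simulate_expression_study(n_null = 40, noise_sd = 0,
                                    plate_scale = 2, seed = 21)
  st2 <- scale_plates(sim2$study)
  expect_equal(st2$expression[, !p1],
               sim2$study$expression[, !p1] / 2, tolerance = 1e-12)
  # equal totals -> identity
  sim0 <- simulate_expression_study(n_null = 40, noise_sd = 0,
                                    plate_scale = 1, seed = 21)
  expect_equal(scale_plates(sim0$study)$expression, sim0$study$expression)
})

test_that("scaling leaves per-gene baseline means comparable across plates", {
  sim <- simulate_expression_study(n_null = 2000, noise_sd = 0.05,
                                   plate_scale = 1.7, seed = 8)
  st <- scale_plates(sim$study)
  m <- st$samples
  gfp <- rowMeans(st$expression[, m$sample_type == "baseline_GFP"])
  mch <- rowMeans(st$expression[, m$sample_type == "baseline_mCh"])
  # same baseline level was planted for both; ratio ~ 1 within noise
  expect_equal(median(gfp / mch), 1, tolerance = 0.02)
})

test_that("filter_annotated keeps the flag conjunction", {
  genes <- data.frame(
    gene_id = sprintf("g%03d", 1:10),
    symbol_present = rep(c(TRUE, TRUE, FALSE, TRUE, TRUE), 2),
    protein_coding = rep(c(TRUE, FALSE, TRUE, TRUE, TRUE), 2)
  )
  st <- typed_study(list(baseline_GFP = 1:10, baseline_mCh = 1:10,
                         MFP = 1:10, AxLN = 1:10, AxLN_LuM = 1:10),
                    genes = genes)
  out <- suppressMessages(filter_annotated(st))
  expect_identical(rownames(out$expression),
                   genes$gene_id[genes$symbol_present & genes$protein_coding])
  all_ok <- st
  all_ok$genes$symbol_present <- TRUE
  all_ok$genes$protein_coding <- TRUE
  expect_identical(filter_annotated(all_ok)$expression, st$expression)
})

test_that("de_vs_baseline applies fold, range and polarity criteria", {
  # gene 1: triplet identical to baselines -> none
  # gene 2: triplet 2x baselines -> up
  # gene 3: triplet at 0.4x -> down
  # gene 4: mean 1.6x but polarity broken by one low replicate -> none
  design <- default_array_design()
  x <- matrix(100, 4, nrow(design),
              dimnames = list(paste0("g", 1:4), design$sample_id))
  trip <- design$sample_id[design$replicate_group == "MFP_t1"]
  x["g2", trip] <- 200
  x["g3", trip] <- 40
  x["g4", trip] <- c(390, 90, 0.1 + 0)  # mean 160.03 > 150, one value below
  dir <- de_vs_baseline(expression_study(x, design), "MFP_t1")
  expect_identical(unname(dir), c("none", "up", "down", "none"))
  # exhaustive cross-comparison oracle for the polarity criterion on g4
  base <- design$sample_id[design$is_baseline]
  polarity_ok <- all(outer(x["g4", trip], x["g4", base], ">"))
  expect_false(polarity_ok)
  expect_error(de_vs_baseline(expression_study(x, design), "GFP"),
               "triplet")
})

test_that("range percentile gate suppresses low-range genes", {
  design <- default_array_design()
  set.seed(99)
  # many wide-range genes, one flat gene whose triplet is still 2x
  x <- matrix(exp(rnorm(50 * nrow(design), log(100), 1)), 50,
              dimnames = list(sprintf("g%02d", 1:50), design$sample_id))
  trip <- design$sample_id[design$replicate_group == "AxLN_t1"]
  base <- design$sample_id[design$is_baseline]
  x["g01", base] <- 1
  x["g01", trip] <- 2.2
  x["g01", setdiff(design$sample_id, c(base, trip))] <- 1
  dir <- de_vs_baseline(expression_study(x, design), "AxLN_t1")
  expect_identical(dir[["g01"]], "none")  # range 1.2 far below 25th pctile
  dir75 <- de_vs_baseline(expression_study(x, design), "AxLN_t1",
                          range_pct = 0)
  expect_identical(dir75[["g01"]], "up")  # gate disabled -> criterion i+iii
})

test_that("separation_pvalue equals exhaustive enumeration for n1+n2 <= 10", {
  for (n1 in 1:5) for (n2 in n1:(10 - n1)) {
    n <- n1 + n2
    sets <- utils::combn(n, n1)
    # complete one-direction separation: group 1 occupies the lowest ranks
    hits <- sum(apply(sets, 2, function(s) all(s == seq_len(n1))))
    expect_equal(separation_pvalue(n1, n2), hits / ncol(sets))
  }
  expect_equal(separation_pvalue(1, 1), 0.5)
  expect_equal(separation_pvalue(2, 3), 0.1)
  expect_error(separation_pvalue(0, 5), ">= 1")
})

test_that("pairwise comparison flags complete separation with the exact p", {
  st <- typed_study(list(baseline_GFP = c(1, 1, 1),
                         baseline_mCh = c(1, 1, 1),
                         MFP = c(1, 5, 3),
                         AxLN = c(2, 1, 3.0),
                         AxLN_LuM = c(1, 1, 2.9)))
  # add tiny deterministic jitter so "interleaved" is meaningful
  set.seed(2)
  st$expression <- st$expression *
    matrix(exp(rnorm(length(st$expression), 0, 0.01)),
           nrow(st$expression))
  cr <- pairwise_type_comparison(st, "MFP", "AxLN")
  expect_equal(cr$n1, 6)
  expect_equal(cr$n2, 9)
  expect_equal(cr$p, 1 / choose(15, 6))
  expect_identical(cr$direction[["g001"]], "up")    # all AxLN above all MFP
  expect_identical(cr$direction[["g002"]], "down")  # all AxLN below all MFP
  expect_identical(cr$direction[["g003"]], "none")  # interleaved
  expect_error(pairwise_type_comparison(st, "MFP", "nope"), "absent")
})

test_that("pattern assignment follows the min-distance tag rule", {
  # worked example: MFP ~1, AxLN ~5, LuM ~1.5 -> LuM nearer MFP -> f
  st <- typed_study(list(baseline_GFP = 1, baseline_mCh = 1,
                         MFP = 1, AxLN = 5, AxLN_LuM = 1.5))
  n <- ncol(st$expression)
  st$expression[1, ] <- st$expression[1, ] +
    seq(-0.05, 0.05, length.out = n)  # within-type spread, no ties
  comps <- list(pairwise_type_comparison(st, "MFP", "AxLN"),
                pairwise_type_comparison(st, "MFP", "AxLN_LuM"),
                pairwise_type_comparison(st, "AxLN", "AxLN_LuM"))
  pt <- merge_and_assign_patterns(st, comps)
  expect_equal(nrow(pt), 1L)
  expect_identical(pt$pattern, "f")
  expect_identical(pt$divergent_type, "AxLN")
  expect_identical(c(pt$tag_MFP, pt$tag_AxLN, pt$tag_AxLN_LuM),
                   c("Down", "Up", "Down"))
  # p is the product of the separation p-values of the flagged comparisons
  flagged <- vapply(comps, function(cr) cr$direction[[pt$gene]] != "none",
                    logical(1))
  expect_equal(pt$p, prod(vapply(comps, `[[`, 1, "p")[flagged]))
})

test_that("negating the matrix flips every pattern to its anti-pattern", {
  sim <- simulate_expression_study(n_null = 100, n_per_pattern = 10,
                                   fold = 2, noise_sd = 0.05, seed = 31)
  st <- sim$study
  run <- function(study) {
    comps <- list(pairwise_type_comparison(study, "MFP", "AxLN"),
                  pairwise_type_comparison(study, "MFP", "AxLN_LuM"),
                  pairwise_type_comparison(study, "AxLN", "AxLN_LuM"))
    merge_and_assign_patterns(study, comps)
  }
  pt <- run(st)
  flipped <- st
  # reciprocal expression reverses every rank while staying positive
  flipped$expression <- 1 / st$expression
  pf <- run(flipped)
  expect_setequal(pt$gene, pf$gene)
  anti <- c(a = "b", b = "a", c = "d", d = "c", e = "f", f = "e")
  expect_identical(unname(anti[pt$pattern[match(pf$gene, pt$gene)]]),
                   pf$pattern)
})

test_that("global rescaling changes no call, pattern or p-value", {
  sim <- simulate_expression_study(n_null = 60, n_per_pattern = 5,
                                   fold = 2, noise_sd = 0.05,
                                   plate_scale = 1.3, seed = 13)
  pt1 <- call_patterns(sim$study)
  scaled <- sim$study
  scaled$expression <- scaled$expression * 37.5
  pt2 <- call_patterns(scaled)
  strip <- function(x) {
    attr(x, "study") <- NULL; attr(x, "comparisons") <- NULL; x
  }
  expect_identical(strip(pt1), strip(pt2))
  d1 <- de_vs_baseline(scale_plates(sim$study), "AxLN_t1")
  d2 <- de_vs_baseline(scale_plates(scaled), "AxLN_t1")
  expect_identical(d1, d2)
})

test_that("tied type means are excluded with a message", {
  st <- typed_study(list(baseline_GFP = 1, baseline_mCh = 1,
                         MFP = 1, AxLN = 2, AxLN_LuM = 1))
  # MFP and LuM means tie exactly; gene is separated in 2 comparisons
  comps <- list(pairwise_type_comparison(st, "MFP", "AxLN"),
                pairwise_type_comparison(st, "MFP", "AxLN_LuM"),
                pairwise_type_comparison(st, "AxLN", "AxLN_LuM"))
  expect_message(pt <- merge_and_assign_patterns(st, comps), "tied")
  expect_equal(nrow(pt), 0L)
})

test_that("cluster_and_split centers rows and splits by the divergent sign", {
  sim <- simulate_expression_study(n_null = 0, n_per_pattern = 8, fold = 2,
                                   noise_sd = 0.02, seed = 17)
  pt <- call_patterns(sim$study)
  split_ef <- cluster_and_split(attr(pt, "study"), pt, c("e", "f"))
  x <- attr(split_ef, "centered")
  expect_equal(unname(rowSums(x)), rep(0, nrow(x)), tolerance = 1e-12)
  # pattern f: AxLN (divergent) above its row mean -> top; e -> bottom
  expect_true(all(split_ef$half[split_ef$pattern == "f"] == "top"))
  expect_true(all(split_ef$half[split_ef$pattern == "e"] == "bottom"))
  # split sizes equal planted counts
  expect_equal(sum(split_ef$half == "top"), 8)
  expect_equal(sum(split_ef$half == "bottom"), 8)
  # top half precedes bottom half in the row order
  expect_true(max(which(split_ef$half == "top")) <
                min(which(split_ef$half == "bottom")))
  split_cd <- cluster_and_split(attr(pt, "study"), pt, c("c", "d"))
  expect_equal(as.vector(table(split_cd$half)), c(8, 8))
  expect_error(cluster_and_split(attr(pt, "study"), pt, c("a", "f")),
               "divergent")
})

test_that("planted patterns are recovered at moderate noise", {
  sim <- simulate_expression_study(n_null = 400, n_per_pattern = 25,
                                   fold = 2, noise_sd = 0.05,
                                   plate_scale = 1.7, seed = 19)
  pt <- call_patterns(sim$study)
  truth <- sim$truth$planted_pattern[pt$gene]
  expect_gte(mean(pt$pattern == truth, na.rm = TRUE), 0.95)
  expect_gte(sum(!is.na(truth)), 0.95 * 150)
})
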