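# lnseed

Do distant metastases arise directly from the primary tumor, or are they
seeded *via* lymph-node (LN) metastases? `lnseed` implements a two-stage
analysis pipeline around that question, for cancer-genomics and
tumor-biology groups working with multi-site patient sampling (primary
tumor, LN metastases, distant metastases, matched normal) and with
microarray comparisons of tumor microenvironments.

## What it computes

**Stage 1 — seeding classification from somatic mutations.** Per-sample
mutation profiles are normalized to probability distributions over
variants and compared with the Jensen–Shannon divergence

    JSD(p, q) = KL(p ‖ m)/2 + KL(q ‖ m)/2,   m = (p + q)/2,

natural log, bounded by log 2. A neighbor-joining tree (deterministic
Saitou–Nei, with documented tie-breaks) is built from the distance matrix
and rooted at the primary sample. A patient is called **LN-met mediated**
iff the rooted tree has a clade containing a distant metastasis and a LN
sample but no primary sample, else **LN-met independent**. Per-sample
distance ratios D_LM/D_LP (per LN) and D_ML/D_MP (per distant metastasis)
quantify which lineage each sample is closer to (ratio < 1: closer to the
LN side). Robustness is scored by bootstrapping variants 1000 times and
reporting `100 × (matching classifications) / iterations`.

**Stage 2 — expression plasticity patterns.** Two microarray plates are
combined after scaling by their cumulative-expression ratio; genes are
filtered to annotated protein-coding; sample triplets are tested against
two pooled quadruplicate baselines (fold ≥ 1.5× / ≤ 0.5×, range ≥ 25th
percentile, consistent polarity); sample types are compared by complete
rank separation, each flagged gene carrying the exact combinatorial
p-value `1 / C(n1+n2, n1)` — with the default 6/9/9 design, 1.9980e-04 for
the MFP comparisons and 2.0568e-05 for AxLN vs AxLN-LuM. Genes flagged in
≥ 2 of the 3 comparisons receive one of six Up/Down tag triples
(a Up-Up-Down … f Down-Up-Down) via a min-distance tagging rule; heat-map
halves are split at the divergent type's sign change; gene-set enrichment
uses the EASE score (Fisher exact on the overlap-decremented table).

**Synthetic data.** `simulate_cohort()` generates patients by dropping
Poisson(λ) mutations on clone-tree branches under a known seeding mode;
`simulate_expression_study()` plants six-way patterns at a chosen fold over
lognormal noise, with a two-plate design. Both record ground truth so
every stage is validated by recovery.

## Worked example

```r
library(lnseed)

## stage 1: simulate one LN-mediated patient and classify it
sp <- simulate_patient("ln_mediated", n_primary = 2, n_ln = 1,
                       n_distant = 2, lambda_mut = 20, seed = 7)
call <- bootstrap_confidence(sp$profile, n_iter = 1000, seed = 1)
call
#> <seeding_call> patient SIM -> LN_met_mediated
#>   bootstrap confidence: 100 / 100 ( 1000 iterations )
#>   LN ratios (D_LM/D_LP):  L1=0.264
#>   met ratios (D_ML/D_MP): D1=0.233, D2=0.264
```

The LN sample sits closer to a distant metastasis than to the primary
(D_LM/D_LP = 0.264 < 1), both metastases are closer to the LN than to the
primary, and all 1000 bootstrap replicates reproduce the LN-met-mediated
call.

```r
## stage 2: plant 25 genes per pattern over 2000 nulls and recover them
sim <- simulate_expression_study(n_null = 2000, n_per_pattern = 25,
                                 fold = 2, noise_sd = 0.05,
                                 plate_scale = 1.7, seed = 11)
pt <- call_patterns(sim$study)
table(pt$pattern)
#>  a  b  c  d  e  f
#> 25 25 25 25 25 25

subset(as.data.frame(pt), pattern == "f")[1:2, c("gene", "tag_MFP",
       "tag_AxLN", "tag_AxLN_LuM", "pattern", "divergent_type", "p")]
#>        gene tag_MFP tag_AxLN tag_AxLN_LuM pattern divergent_type            p
#> 126 g002126    Down       Up         Down       f           AxLN 4.109424e-09
#> 127 g002127    Down       Up         Down       f           AxLN 4.109424e-09
```

All 150 planted genes are recovered into their true patterns and no null
gene is flagged. Pattern f (Down-Up-Down) genes are up only in the LN
tumors — the reversible, LN-specific regulation the pipeline is designed
to find; their per-gene p is the product of the two flagged comparisons'
exact separation p-values (1/5005 × 1/48620 ≈ 4.1e-09).

A thin command-line wrapper over the same functions ships in
`inst/cli/lnseed.R` (subcommands `simulate-cohort`, `simulate-array`,
`phylo-classify`, `pattern-call`, `enrich`).

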