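---
title: "Methods: seeding phylogenies and expression plasticity patterns"
author: "lnseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seeding phylogenies and expression plasticity patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnseed)
```

# Overview

`lnseed` implements two analysis stages for the question of whether distant
metastases are seeded *via* lymph-node (LN) metastases or directly from the
primary tumor:

1. **Seeding classification** (`classify_patient()`,
   `bootstrap_confidence()`): per-patient phylogenetic analysis of
   somatic-mutation profiles across primary, LN-metastasis and
   distant-metastasis samples.
2. **Plasticity-pattern calling** (`call_patterns()`,
   `ease_enrichment()`): identification of genes regulated specifically in
   LN tumors from a two-plate microarray study over three tumor
   microenvironments.

A synthetic-data module (`simulate_cohort()`,
`simulate_expression_study()`) generates inputs with known ground truth so
both stages can be validated by recovery.

# Stage 1: seeding classification

## Distance model

Each tumor sample contributes a vector of non-negative weights over the
patient's somatic variants (binary presence calls by default, optionally
variant-allele fractions). The vector is normalized to a probability
distribution $p$ over variants, and samples are compared with the
Jensen–Shannon divergence

$$\mathrm{JSD}(p, q) = \tfrac12 KL(p \,\|\, m) + \tfrac12 KL(q \,\|\, m),
\qquad m = \tfrac{p+q}{2},$$

with natural logarithms and $0\log 0 = 0$. The divergence is symmetric,
bounded by $\log 2$, and its square root is a metric. `pairwise_distances()`
returns the divergence by default; `use_sqrt = TRUE` switches to the metric
square root. The default follows the convention of the established
microbiome-ecology implementation of the JSD, against which our
implementation agrees to machine precision in the test suite. Distances are
computed between tumor samples only: matched normals and samples flagged as
low-purity are excluded, as are samples whose weight vector is all zero
(these cannot be normalized).

## Tree, rooting and the clade rule

`nj_tree()` is a deterministic Saitou–Nei neighbor-joining implementation:
taxa are sorted lexicographically, ties in the Q-criterion are broken by the
lowest (row, column) index pair, and negative branch lengths are retained
but reported. Determinism matters because the bootstrap must be exactly
reproducible from a seed. Downstream logic never reads branch lengths —
classification uses only the topology, and the distance ratios use only the
distance matrix — so retaining negative lengths is harmless. For additive
matrices the tree reproduces the input distances exactly, and on random
matrices the topology matches the reference implementation in `ape`.

The tree is rooted at the primary sample (`root_at_primary()`). With
several primary samples the one with the smallest mean distance to the
non-primary samples is chosen, ties broken by lexicographic sample id; a
deterministic rule is required because the procedure is defined with respect
to "the" primary.

`classify_seeding()` scans every clade of the rooted tree and returns
`LN_met_mediated` iff some clade contains at least one distant metastasis,
at least one LN sample and **no** primary sample; otherwise
`LN_met_independent`. The rule is implemented literally. One consequence,
found during development, is that it is degenerate for patients with a
single primary sample: after rooting at that sample its sibling clade is
the entire rest of the tree, which contains every LN and distant sample and
no primary, so such patients are always called mediated. Informative
classification requires at least two primary samples, and the cohort
simulator therefore defaults to two.

## Distance ratios

For each LN sample, $D_{LM}/D_{LP}$ compares its shortest distance to any
distant metastasis with its distance to the (nearest) primary; for each
distant metastasis, $D_{ML}/D_{MP}$ compares its shortest distance to any
LN sample with its distance to the primary. Ratios below 1 indicate
proximity to the LN lineage. Zero denominators (a sample identical to the
primary) make the ratio undefined; such ratios are returned as `NA` with a
warning rather than inventing a value.

## Bootstrap confidence

`bootstrap_confidence()` resamples variants (matrix rows) with replacement
to the original count — the conventional phylogenetic bootstrap unit — and
repeats the whole pipeline per replicate; the confidence score is
$100 \times$ the fraction of replicates reproducing the full-data call.
The resampling scheme is not uniquely determined by the verbal description
"repeated random sampling of the mutation data", so an alternative
without-replacement subsample (`resample_fraction`) is exposed for
sensitivity analysis. Replicates that drop a sample (all-zero resampled
vector) continue without it, mirroring the distance-stage policy;
replicates on which classification is impossible count as non-matches, a
conservative choice. Variants are stored in canonical (lexicographic)
order, so the bootstrap is invariant to the order in which variants were
supplied.

# Stage 2: plasticity-pattern calling

## Plate scaling and annotation filter

The two hybridization plates are combined after multiplying plate 2 by the
ratio of the plates' cumulative (summed) expression. This equalizes totals
exactly, which is only an unbiased correction when both plates carry the
same number of arrays — the default design therefore balances the 32 arrays
16/16, with one baseline quadruplicate per plate. `filter_annotated()`
keeps genes with an associated symbol that are annotated protein-coding;
annotation is supplied as per-gene flags so the filter is a pure input
criterion.

## Differential-expression criteria

`de_vs_baseline()` flags a gene for one experimental triplet when three
criteria hold against the eight pooled baseline replicates:

* **(i) fold change** — triplet mean $\ge$ 1.5× (up) or $\le$ 0.5× (down)
  the pooled-baseline mean. The criterion is stated in the source protocol
  as "$\ge$50% or $\le$50% than the average"; the 1.5×/0.5× fold-change
  reading is adopted because it is the only interpretation yielding two
  distinct cutoffs, and both thresholds are configurable.
* **(ii) range** — the gene's range (max − min) over the 11-sample
  submatrix (8 baselines + triplet) is at or above the 25th percentile of
  all genes' ranges in that submatrix (linear interpolation, ties
  retained).
* **(iii) polarity** — all 3 × 8 comparisons between triplet samples and
  baseline replicates have the same sign. Pooling all eight baseline
  replicates (rather than each quadruplicate separately) is the stricter
  reading and is used throughout.

## Pairwise comparisons and exact p-values

Sample types are compared directly by complete rank separation: a gene is
flagged when every value of one type exceeds every value of the other
(`pairwise_type_comparison()`). Under exchangeability the probability of a
fixed-direction complete separation is exactly

$$p = \binom{n_1 + n_2}{n_1}^{-1},$$

the per-gene p-value attached to every flagged gene
(`separation_pvalue()`). With the default 6 MFP / 9 AxLN / 9 AxLN-LuM
design this gives $1/\binom{15}{6} = 1.9980\times 10^{-4}$ for the two
MFP comparisons and $1/\binom{18}{9} = 2.0568\times 10^{-5}$ for
AxLN vs AxLN-LuM; the 6/9/9 replicate design is itself reconstructed from
these two values, since each is produced by exactly this combination of
group sizes. The test suite verifies the formula against exhaustive
enumeration of all arrangements for $n_1+n_2 \le 10$, and against the
empirical flag rate of a million simulated null genes (expectation
$2/\binom{n_1+n_2}{n_1}$, both directions).

## Pattern assignment

Genes flagged in at least two of the three comparisons are retained. Per
gene, the sample type with the highest mean is tagged Up, the lowest Down,
and the intermediate type inherits the tag of the nearer extreme under
$d(X, Y) = \min_{i,j} |x_i - y_j|$ computed over all samples of the two
types. The (MFP, AxLN, AxLN-LuM) tag triple is one of six patterns —
a Up-Up-Down, b Down-Down-Up, c Up-Down-Down, d Down-Up-Up, e Up-Down-Up,
f Down-Up-Down — forming the pattern/anti-pattern couples a/b, c/d, e/f.
Exactly tied type means have probability zero under continuous noise; when
they do occur the gene is excluded and reported, not tie-broken. The
merged table's per-gene `p` is the product of the separation p-values of
the comparisons that flagged the gene (the joint probability of the
observed separations under exchangeability); per-comparison directions and
Benjamini–Hochberg q-values are reported alongside.

## Clustering and the top/bottom split

For each pattern couple, `cluster_and_split()` log2-transforms the genes'
expression over the experimental samples, subtracts row means, and orders
rows by hierarchical clustering with average linkage on
$1 - r$ (Pearson) row distances — the common configuration of the classic
open-source clustering tools. The heat map is split where the divergent
sample type (the one whose tag differs from the other two) changes sign;
membership is equivalently the sign of the divergent type's centered mean,
which is independent of row order, so the clustering choice affects
presentation only and cannot change downstream results.

## EASE enrichment

`ease_score()` is the conservative gene-set enrichment p-value: the
one-sided Fisher exact test on the 2×2 list-by-term table after
decrementing the overlap cell by one (floored at zero), so single-gene
overlaps can never be significant. Terms are declared significant at
p < 0.01. Gene sets are supplied as GMT; no annotation database is bundled
or downloaded.

# The synthetic-data generator

## Mutation cohorts

`simulate_patient()` builds a clone tree, draws a Poisson($\lambda$) number
of mutations on every branch ($\lambda = 20$ per branch by default — enough
signal that noiseless classification is unambiguous while keeping matrices
small), and gives each sample the union of mutations along its clone's root
path. Under LN-mediated seeding the distant clones are children of the
first LN clone; under LN-independent seeding each distant clone descends
from a primary subclone (round-robin over primaries), i.e. is seeded
hematogenously from the primary tumor. The subclone structure gives every
internal split its own mutation branch, so the noiseless distance matrix
supports a unique NJ resolution; a star-like alternative (all clones off
the common ancestor) would leave the topology to tie-breaking.

Call noise consists of false negatives (each true call dropped with
`fn_rate`) and false positives planted into a global pool of never-true
variant ids (size max(10, 10% of true variants)), so the variant universe
is fixed and bootstrap resampling remains well defined. The rates are free
parameters, not estimates of any particular sequencing pipeline's error
profile. Binary calls can be degraded to pseudo-VAFs via
Beta(20·call + 1, 20·(1 − call) + 1) draws; binary is the default because
the upstream analysis is defined on detected mutations.

`simulate_cohort()` assigns exactly `round(n_patients * fraction)` patients
the LN-mediated truth — so a 7-patient cohort at fraction 5/7 contains
exactly 5 — and shuffles the order under the seed.

## Expression studies

`simulate_expression_study()` draws a lognormal baseline level per gene
(median 100, log-sd 0.5, an arbitrary but realistic intensity scale) and
multiplies every sample by lognormal noise (`noise_sd` on the log scale;
default 0.05, a typical replicate CV for summarized array data). Planted
genes have all samples of Up-tagged types multiplied by `fold` (default 2);
Down-tagged types and baselines stay at the gene's baseline level, so e.g.
pattern f at fold 2 puts AxLN at exactly twice everything else in the
noiseless limit. Plate 2 is finally multiplied by `plate_scale` to emulate
a between-plate intensity difference.

What the generator does *not* emulate: probe-level effects and RMA
summarization, correlated (batch-structured) noise, heavy-tailed outliers,
mixed or partial regulation within a sample type, and realistic
gene–gene correlation. Passing recovery tests therefore demonstrates that
the calling algorithm is correct under its own statistical assumptions, not
that those assumptions hold for any particular real array study.

# Validation by recovery, and problem sizes

The test suite and the acceptance script validate by recovery at these
sizes, chosen to give stable statistics at interactive runtimes:

* 50-patient cohorts at $\lambda = 20$, two primaries / one LN / two
  distants per patient: noiseless classification agrees with the simulated
  truth in 100% of patients, and agreement is non-increasing across
  fn = fp ∈ {0, 0.05, 0.2}.
* Bootstrap confidence (1000 iterations) on noiseless $\lambda = 50$
  patients of both seeding modes.
* Pattern recovery on 5000 null + 504 planted genes (84 per pattern) at
  fold 2, noise 0.05, plate scale 1.7.
* Null flag rate of the separation comparisons on $10^6$ simulated null
  genes, compared with $2/\binom{n_1+n_2}{n_1}$ within three binomial
  standard errors.
* EASE scores against an independent hypergeometric-tail summation on 1000
  random contingency tables.

# Known limitations

* The clade rule is literal; behavior when a clade contains both LN and
  primary samples alongside distants is "not mediated", and single-primary
  patients are degenerate (see above).
* JSD on binary call profiles discards allele-fraction information; the
  pseudo-VAF option exists but the upstream convention (calls vs VAFs) is
  an open question of the source protocol.
* The plate-scaling rule assumes comparable array counts and compositions
  per plate; strongly unbalanced plates bias cross-plate comparisons.
* The per-comparison replicate sizes (6/9/9) are a reconstruction from the
  printed p-values; other designs are supported by supplying metadata, with
  p-values recomputed from the actual group sizes.
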