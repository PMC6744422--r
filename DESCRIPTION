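Package: lnseed
Title: Lymph-Node Seeding Classification from Tumor Phylogenies and
    Expression Plasticity Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis pipeline for studying whether distant
    metastases are seeded via lymph-node (LN) metastases. Stage one
    classifies each patient as LN-met mediated or LN-met independent from
    somatic-mutation profiles: Jensen-Shannon divergence distance
    matrices, neighbor-joining trees rooted at the primary tumor,
    LN/metastasis distance ratios, a clade rule, and bootstrap confidence
    scores. Stage two calls six-way expression "plasticity patterns"
    (Up/Down tag triples over three tumor microenvironments) from
    two-plate microarray studies, with exact rank-separation p-values per
    gene and EASE-score gene-set enrichment. A synthetic-data module
    simulates clonal mutation accrual along known seeding topologies and
    expression studies with planted patterns, so both stages can be
    validated by recovery of simulated ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    optparse,
    phangorn,
    phyloseq,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
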