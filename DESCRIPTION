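Package: scmetaz
Title: Case/Control Single-Cell PBMC Pipeline with Metagene Z-Scoring
Version: 0.1.0
Authors@R: person("PBMC", "Pipeline Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A tested pipeline for case/control single-cell PBMC cohort
    analysis: reference-panel projection and multi-resolution cell-type
    annotation, quality-control filters, cell-composition statistics and
    kNN case-enrichment in expression space, pseudo-bulk negative-binomial
    differential expression with evidence-weighted effect scores,
    DEG-module and gene-set enrichment analysis, a per-cell-type metagene
    z-score (TMZ) with molecular subtyping and bulk RNA-seq projection,
    and gene-level GWAS covariate enrichment with effector-gene selection.
    Includes a synthetic-cohort generator so every stage is testable
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
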