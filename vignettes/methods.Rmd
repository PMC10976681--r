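---
title: "Methods: case/control PBMC pipeline and the TMZ metagene score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case/control PBMC pipeline and the TMZ metagene score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`scmetaz` implements the bespoke computations of a case/control
single-cell PBMC study design: reference-projection cell annotation,
composition and neighbourhood-enrichment statistics, pseudo-bulk
negative-binomial differential expression, DEG-module and gene-set
enrichment analysis, a per-cell-type metagene z-score (the "TMZ score")
with molecular subtyping and bulk RNA-seq projection, and a gene-level
GWAS covariate analysis with effector-gene selection. Every stage is
exercisable on a bundled synthetic-cohort generator, so the whole
pipeline is testable without access to restricted patient data.

## The count model

All simulated UMI counts are negative binomial with the
mean-dispersion parameterization `var = mu + phi * mu^2`. This is the
same family the pseudo-bulk differential test assumes, which makes
parameter recovery well-posed: what the generator plants, the test can
in principle estimate without model mismatch.

## The shared-activation structure

The central biological claim the package encodes is that case samples
carry a *shared* immune-activation strength: one latent scalar
`alpha_s` per case sample that scales every planted per-cell-type
log2 fold-change in that sample. `alpha_s` is log-normal with mean 1
(`activation_sd`, default 0.4, is the log-scale sd); controls have
`alpha_s = 0`. Because all of a sample's cell-type programs move
together, the per-cell-type TMZ scores of a cohort are strongly
correlated across samples — the structure behind the headline
acceptance target (minimum pairwise Pearson correlation of the 13 TMZ
columns at least 0.9). A discrete variant (`activation_tiers`) plants
low/intermediate/high activation groups for subtype-recovery tests.

# The synthetic cohort: what it emulates and what it does not

Defaults are chosen once as the stated world and not revisited:

| parameter | default | reason |
|---|---|---|
| `n_case`, `n_control` | 46, 31 | the emulated cohort's arm sizes |
| `cells_per_sample` | 400 | desk-scale stand-in for thousands of QC-passed cells per donor |
| `cell_types` | 13 PBMC types | T, NK, B, monocyte sub-populations with realistic blood fractions |
| `genes` | 2000 | large enough for 13 disjoint 80-gene DE programs plus 30 markers per type |
| `de_spec` | 40 up + 40 down per type, mean |log2FC| = 1 | free parameter (the source protocol states no effect-size distribution); |log2FC| is Gamma(shape 2) — many moderate effects, a few strong ones, as in real DEG tables |
| `activation_sd` | 0.4 | gives case/control TMZ separation without degenerate overlap |
| `doublet_rate` | 0.05 | typical droplet chemistry rate |
| `mito_mean`, `mito_sd` | 0.03, 0.015 | healthy PBMC mitochondrial fractions; the 7% QC cut removes a small tail |
| `dispersion` | 0.3 | cell-level NB overdispersion in the UMI regime |
| `depth_mean`, `depth_sdlog` | 1500, 0.3 | per-cell depth factor (the only library-size heterogeneity modelled) |
| `dirichlet_conc` | 150 | moderate sample-to-sample composition variability |

Planted DE programs are **disjoint across cell types** (the emulated
study reports largely non-overlapping per-cell-type DEG sets); marker
("feature") genes are disjoint 30-gene blocks eight-fold elevated over
baseline. Five X-linked and five Y-linked genes switch with the
sample's sex; ten `MT-` genes are rescaled per cell to a Beta-drawn
mitochondrial fraction. Doublets are sums of two cells' expected
profiles at doubled depth — sufficient for testing exclusion plumbing,
not a model of chimeric transcriptomes. A 40-gene "HLA-like" block on
chr6:25–35 Mb always carries elevated genetic risk scores so that
region-exclusion logic is exercised.

Not emulated: ambient RNA, batch chemistry effects, gene–gene
correlation beyond the type/activation structure, realistic library
size distributions, UMI saturation. A green test therefore establishes
that the *statistical machinery* behaves as specified on data with the
assumed generative structure — not that the pipeline is robust to
artefacts absent from that structure.

Gene-level risk scores (`generate_gene_risk_scores`) give every gene
an Exp(1) baseline (the scale of −log10 gene-level p-values); a
fraction `signal_frac` of the causal cell types' planted DE genes gain
a Gamma(shape 2) elevation whose mean is proportional to the gene's
planted |log2FC|. The proportionality is deliberate: the covariate
test regresses risk on normalized DES *within* a cell type's
significant genes, so a positive control must couple risk to effect
size, not merely to set membership. Gamma(shape 2) rather than
exponential keeps a few extreme scores from dominating the OLS slope.

# Stage-by-stage numerical choices

## Quality control

"Expressed" means count > 0 throughout. Gene prevalence uses
`ceiling(min_frac * n_cells)` so the 0.1% rule keeps a gene seen in 1
of 1000 cells. NODG (number of detected genes) windows are strict on
both sides (`low < NODG < high`), with per-cluster windows (pDC,
platelet, ...) falling back to (500, 2500). NODG and the mitochondrial
fraction are computed before gene filtering; the pipeline order is
genes-first and the tests pin that order. The mitochondrial gene set is
a configurable name-prefix convention (default `MT-`). The
sex-concordance check compares per-sample summed log1p Y-gene
expression to the midpoint of the two annotated-sex group means; with
a single-sex cohort the threshold is undefined and only scores are
returned.

## Normalization and projection

Cells are scaled to a fixed 10,000-count target and log1p-transformed.
A fixed target (rather than the cohort median depth) is what makes the
projection exactly invariant to per-cell or global count rescaling;
the correlation statistic downstream only needs a monotone
variance-stabilizing transform.

Projection computes the Pearson correlation between each cell and each
reference-panel row over shared feature genes, then applies a
**sign-preserving** fourth power `sign(r) * |r|^4`. A plain even power
would conflate strong negative with strong positive correlation; sign
preservation keeps the sharpening while retaining direction. Scores
are then z-scored within each panel row across cells; zero-variance
rows are exempted and flagged, and cells constant across feature genes
get missing scores.

## Clustering and annotation

Cell clustering uses the correlation distance `1 − r` between
projection columns, average-linkage hierarchical clustering, and a
deterministic replacement for an external dynamic tree-cut: a branch is
split into its two dendrogram children only while both children hold at
least `min_cluster_size` cells (default 20) and the two-way split has
strictly positive mean silhouette width within the branch. Identical
columns therefore stay in one cluster, and clean blocks split exactly
once. kNN and k-means style ties are broken by index for determinism; a
fixed-`k` fallback exists.

Cluster annotation assigns the argmax panel type when its mean z-score
reaches `z_min` and leads the runner-up by `margin`, else the cluster
is "ambiguous" and its cells are excluded downstream. Defaults are
`z_min = 0.25`, `margin = 0.25`. An earlier draft used `z_min = 1`,
but for row-z-scored projections a cluster containing fraction `p` of
all cells has mean own-type z of `sqrt((1-p)/p)`, which is below 1
whenever `p > 0.5` — a threshold of 1 brands every abundant,
perfectly separated type ambiguous. 0.25 corresponds to `p ≈ 0.94`
and still rejects clusters with no correlation structure.

Multi-resolution annotation projects all cells with the major panel,
then re-clusters each compartment's cells against its ordered
subpanels; cells confidently annotated by an earlier subpanel are
fixed, the rest move to the next subpanel (mirroring sequential
fine-typing of T cells). Cells of ambiguous major clusters never enter
sub-annotation.

## Composition statistics

Proportions are percentages of all annotated cells per sample, with
optional configured ratios (e.g. effector-memory over regulatory T);
zero denominators yield missing values. The covariate regression is
ordinary least squares with Gaussian response and linear terms only —
the additive-model special case the protocol describes — with
per-coefficient partial F-tests (equal to squared t). Collinear
designs fail loudly, naming the aliased columns.

The neighbourhood enrichment field takes each cell's 50 nearest
Euclidean neighbours in 30-component PCA space and computes
`log2(((n_case + c)/(n_ctrl + c)) / (N_case/N_ctrl))` with pseudocount
`c = 0.5`. The global-ratio normalization centres the null at zero;
the pseudocount keeps single-class neighbourhoods finite. The
implementation keeps the statistic as a difference of logarithms so
that swapping the labels negates it bitwise when `c = 0`. Note a
fundamental floor on the null magnitude: for a balanced cohort the
neighbourhood case count is Binomial(50, 1/2), so the expected |e| is
about 0.32 at `k = 50` regardless of implementation; `k` must grow to
shrink it.

## Pseudo-bulk differential expression

Per (sample, cell type), UMI counts are summed; pairs under 5 cells
are excluded, and per cell type genes detected (pseudo-bulk count > 0)
in fewer than `ceiling(0.05 × samples)` retained samples are dropped.
Types with fewer than 3 retained samples in either arm are skipped.
CD4/CD8 sub-populations can be merged pre-DE via a label map.

The test is a deliberately minimal NB-Wald pipeline rather than a
wrapper: median-of-ratios size factors (genes with any zero skipped
from the geometric-mean reference), per-gene method-of-moments
dispersion pooled within condition groups, a Gamma-GLM trend fit
`phi = a0 + a1/mean`, 50/50 log-scale shrinkage of gene dispersion
toward the trend, an NB GLM (log link, intercept + condition, offset =
log size factor) fit by IRLS, and a normal-approximation Wald test with
BH correction per cell type. When no gene shows overdispersion (e.g.
exactly proportional toy data) the estimator stays in the Poisson
limit, which pins the closed-form LFC oracle. Optional LFC shrinkage
uses a single normal prior whose variance is the excess of observed
LFC variance over squared standard errors. Unconverged genes carry
missing p-values and are excluded from DES ranking.

DEGs are `|log2FC| >= log2(1.3)` and `q <= 0.1`, both boundaries
inclusive. The source protocol states 0.05 in one place and 0.1 in
another for the same definition; the package defaults to 0.1 and
surfaces the choice as an argument plus a message. The differential
expression score is `DES = |log2FC| × (−log10 q)` for every converged
gene.

## Enrichment

The DEG-module step runs multi-restart k-means (default k = 8,
best inertia kept) on the DEGs × cell-types log2FC matrix with
zero-imputation for untested genes (missing = no evidence of change).
Overlap testing is the one-sided Fisher exact test computed as the
exact hypergeometric upper tail, BH-corrected across requested pairs;
over-representation analysis is the same statistic against a gene-set
collection with size bounds (10–500 by default). Redundant terms are
not pruned; a Jaccard-similarity matrix is reported instead.

Preranked GSEA is unweighted (exponent 0): the running sum gains
`1/|S|` at set members and loses `1/(N−|S|)` elsewhere; the ES is the
signed maximal deviation. A set containing every ranked gene has no
misses; the sum climbs monotonically to 1 and the ES is pinned to 1 by
the brute-force oracle. The ranking metric is `sign(log2FC) × DES`
(DES is unsigned; GSEA needs direction). The null permutes gene labels
— after differential expression only a ranked list exists, so
phenotype permutation is unavailable — and
`NES = ES / mean |null ES of matching sign|`. This is a documented
reimplementation, not bit-compatible with any external tool.

## TMZ scoring, subtyping, and bulk projection

Pseudo-bulk expression is normalized to log2-CPM (the z-transform
scale is otherwise unstated; the log scale stabilizes variance), each
DEG is z-scored across samples, and
`TMZ_i = mean(z over up-DEGs) − mean(z over down-DEGs)` per cell type
`i`; the average TMZ is the mean over non-missing cell types.
Zero-variance genes are dropped with a warning. Because z-scores are
centred, every TMZ column has mean zero over samples.

Subtyping k-means the samples × cell-types TMZ matrix (k = 3) after
imputing each sample's missing entries with its own mean — the
observed global-activation level is exactly the quantity being
clustered, so mean imputation preserves it. Clusters are renamed
low/intermediate/high by mean average-TMZ, making labels monotone by
construction. Clinical association uses OLS with partial F-tests
(sex, GADA titer, HLA-risk count, optionally age), Spearman rank
correlation against GADA, and Kruskal–Wallis across HLA categories.

For bulk projection, per-cell-type DEG sets are unioned into three
compartments (T/NK, B, monocyte); genes appearing in both the up and
down union are dropped from both (sign ambiguity). Compartment scores
computed on bulk data (z across bulk samples when n ≥ 3, else z
anchored to reference gene means/sds so a single sample can be scored)
are mapped onto the reference TMZ distribution by empirical-quantile
interpolation between order statistics — rank-preserving by
construction, with the median bulk sample landing on the reference
median. Paired designs are evaluated with a paired t-test.

## GWAS covariate analysis

Genes with `q < 0.1` are retained and their DES min-max normalized to
[0, 1] per cell type. (The protocol sentence "genes with q < 0.1 were
filtered out and DES of remaining genes were normalized" contradicts
itself — removing significant genes would leave only nulls to rank —
so the package retains the significant genes and documents the
reading.) The external gene-scoring tool is replaced by an in-house
one-sided OLS of the supplied gene risk score on normalized DES over
the shared gene set: those tools need genome-scale LD reference data,
while the artifact's contract is the DES-conditioning logic with
scores as input. The test runs genome-wide and with an excluded region
(default chr6:25–35 Mb, the HLA convention on GRCh37), BH across cell
types. Effector genes are the intersection of the top 200 genes by
risk score with the genes at or above the 70th percentile of
normalized DES ("top 30 percentile" read as the upper 30%); the set is
monotone in both knobs.

# Reproducibility

One config seed is split into per-stage sub-seeds by a deterministic
hash (`stage_seed`), all below 2^31. Two runs with the same config and
seed produce byte-identical outputs; the pipeline writes an MD5
manifest to make this checkable. Configs serialize to JSON and
round-trip exactly.

# Known limitations

* The NB Wald test uses a normal approximation with plug-in shrunk
  dispersions; at very small sample sizes (3–5 per arm) it is mildly
  anti-conservative, as all Wald-type count tests are.
* The dynamic-cut replacement is top-down and cannot rescue a split
  whose first binary division is unbalanced below `min_cluster_size`.
* The GSEA NES normalization is permutation-based and differs
  numerically from analytic or tool-specific NES values.
* The neighbourhood-enrichment null magnitude is bounded below by
  binomial sampling noise at the chosen `k` (see above); treat per-cell
  values as a field to smooth or threshold, not as significance.
* Single-sample bulk projection inherits whatever scale mismatch
  exists between the bulk platform and the reference gene statistics;
  only the rank map, not the raw score, is interpretable.
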