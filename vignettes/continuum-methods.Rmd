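---
title: "Methods: the malignant continuum and its companion analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the malignant continuum and its companion analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical model behind each analysis step, the
default parameters and why they were chosen, what the simulator does and does
not generate, and the numerical decisions that make results deterministic.
Code chunks are illustrative and not evaluated.

## 1. Input model and preprocessing

A `count_dataset` holds a sparse cells-by-genes count matrix, per-cell
metadata (`barcode`, `sample_id`, `stage`, `cell_type`) with stages drawn
from the serrated progression `normal < HP < SSL < SSLD < TSA < tumor`, and a
gene annotation (`gene_id`, `gene_name`, `chromosome`, `start`, `end`,
`arm`). `qc_filter()` keeps cells with at least `min_genes = 200` detected
genes and at most `max_mito_pct = 20` percent mitochondrial counts
(recognised by the `"MT-"` gene-name prefix); it refuses to empty a sample,
because every downstream analysis is per-sample. `normalize_counts()` maps
counts to `ln(1 + count * 10000 / libsize)` — the standard log-normalization;
all downstream "expression" means this quantity.

## 2. Hurdle differential expression

Single-cell expression is zero-inflated: a gene can differ between groups in
how often it is detected, in how strongly it is expressed when detected, or
both. `hurdle_de()` therefore combines two parts per gene:

* detection: a two-proportion z-test on the expressed-cell fractions, with
  pooled standard error; undefined when the pooled rate is 0 or 1;
* magnitude: a Welch t-test on normalized expression among expressing cells,
  computed from sparse column sums; undefined with fewer than two expressing
  cells in a group.

The parts are combined with Fisher's method (χ², df 4; df 2 when only one
part is defined). Genes detected in less than `min_pct = 0.05` of the cells
of *both* groups are skipped, and groups under `min_cells = 10` make the
whole comparison return `NULL` rather than noisy results. The reported fold
change de-logs before averaging and uses a pseudocount of one:
`log2fc = log2((mean(expm1(x_t)) + 1) / (mean(expm1(x_r)) + 1))`, so it is a
fold change of average expression, not an average of per-cell fold changes.

**Limitation.** Both parts are asymptotic approximations. On null data their
p-values pass a Kolmogorov–Smirnov uniformity check comfortably in the bulk,
but the extreme tail (p below about 1e-5) is mildly heavy — skewed expression
breaks the t approximation at 4–5 sigma. Benjamini–Hochberg selection over
thousands of genes probes exactly that region, so on a pure-null dataset of
5000 genes a single false BH discovery is somewhat more likely than the
nominal 5%. A rank-based fallback (`method = "wilcox"`) is available when
calibration matters more than power.

## 3. Continuum construction

`profile_all_samples()` pools the target subtype's cells from all
normal-stage samples into one reference and profiles every other sample
against it, BH-adjusting within sample. `select_continuum_genes()` keeps
genes with `p_adj < 0.05` in at least `min_samples = 2` samples — one
significant sample could be sample-specific biology or noise; two is the
weakest reproducibility requirement. `continuum_pca()` builds the
samples-by-genes log2FC matrix (entries a sample never tested are imputed as
0, "no evidence of change", with a message), column-centers without scaling —
scaling would equalise strong and weak responders, and log2FC units are
already comparable across genes — and orients each component so its
largest-magnitude loading is positive, which removes the PCA sign ambiguity
deterministically.

`fit_principal_curve()` implements the Hastie–Stuetzle alternation in the
PC1/PC2 plane: initialise arc-length positions from PC1, smooth each
coordinate against position (`smooth.spline`, with a linear fallback for
exactly collinear or degenerate configurations so that collinear input
reduces *exactly* to line projection), evaluate the curve on a 200-point
grid, re-project the samples onto the polyline, and iterate until the mean
projection displacement falls below `tol = 1e-4` (at most 30 iterations; a
warning reports non-convergence). Positions are rescaled to [0, 1] and
oriented so the earliest pathological stage present has the smaller mean
position. `gene_trends()` correlates per-sample log2FC with a continuum axis
by Spearman rank correlation. The default axis is PC2, mirroring analyses
where the malignancy signal lands on the second component; with the
package's simulator the planted continuum is one-dimensional, the signal
loads on PC1, and the principal-curve `position` axis is the meaningful
choice.

## 4. Copy-number inference from expression

`relative_expression()` subtracts, per gene, the mean normalized expression
of a reference cell population (normal-stage cells) and clips to ±3 to bound
outlier influence. `smooth_by_position()` replaces each gene's value by a
moving average over its `window = 101` genomic neighbours on the same
chromosome (the window shrinks symmetrically at chromosome edges and never
crosses a boundary): single-gene variation is expression noise, while
coherent shifts across ~100 consecutive genes are copy-number-like dosage.
`cnv_score()` summarises each cell by the mean squared smoothed deviation —
zero exactly for a neutral profile, scale-stable across gene counts.
`arm_events()` averages smoothed profiles over each sample's non-reference
cells (samples consisting entirely of reference cells use all their cells)
and reports the percentage of arm genes above `gain_thr = 0.1` or below
`-loss_thr = 0.1`.

**Limitation.** The per-cell score aggregates over *all* genes, so its
sensitivity to a single planted arm scales with that arm's share of the
annotation; a stage comparison of scores (Kruskal–Wallis) can be
unremarkable even when arm-level gain calls are unambiguous.

## 5. Module scores and cell-cycle phases

`module_score()` is a control-matched score: mean expression of the set
genes minus mean expression of `n_ctrl = 100` control genes drawn, per set
gene, from the same average-expression bin (`n_bins = 25` bins over ranked
gene means, set genes excluded; sampling is seeded and deterministic). The
control subtraction cancels cell-wide effects such as depth, so the score
reflects program-specific activity in natural-log expression units.
`assign_phase()` labels a cell G1 when both the S and G2M scores are
nonpositive, otherwise the phase of the larger score (ties to S).

## 6. Composition testing

`proportions_by_sample()` tabulates within-sample cell-type proportions with
explicit zero rows for absent types. `pairwise_stage_test()` compares one
type's per-sample proportions between two stages with a two-sided Wilcoxon
rank-sum test — exact for group sizes up to 10, tie-corrected normal
approximation otherwise — and maps p-values to the star convention NS
(p > 0.05), `*` (p < 0.05), `**` (p < 0.01), `***` (p < 0.001); boundaries
fall in the weaker class. Groups with fewer than two samples are flagged
untestable rather than raising an error.

## 7. The simulator and its scope

`simulate_dataset()` draws each count from a negative binomial with mean

    libsize_c * baseline_g * 2^(beta_g * s(sample(c))) * copy_ratio * 2^elevation

and variance `mu + mu^2 * dispersion`. Baselines are log-normal
(`meanlog log(2)`, `sdlog 1.2`), library-size factors log-normal
(`0, 0.35`), dispersion 0.5 — values giving realistic sparsity at
single-cell depth. The progression score `s` lives on [0, 1]; by default
samples are ranked by (stage order, index) and spaced equally. Continuum
slopes `beta` (default 200 genes, |beta| uniform in [1, 3] log2 units,
random sign) are planted outside CNV arms and program sets; CNV segments
multiply the mean of arm genes in masked cells by `copy_ratio`; programs
elevate their gene set in a disjoint random cell mask by `2^log2_elevation`.
The returned `sim_truth` carries every planted parameter, enabling
parameter-recovery tests.

The generator is deliberately simple: one latent axis, hard segment
boundaries, no batch effects, no doublets or ambient RNA, no gene-gene
correlation beyond the planted structure. It validates the estimators'
mechanics, not their robustness to real-data artefacts.

## 8. Determinism and the pipeline

`run_pipeline()` executes simulate → qc → composition → cnv → score →
continuum from one validated config (unknown keys are errors). A single
global seed fans out into a named substream per stage, so toggling one stage
never perturbs another's randomness. Result tables are TSVs with
'#'-prefixed provenance headers (parameters and seed; no timestamps), which
makes re-runs with identical config byte-identical; `report.json` records
per-stage status, parameters, output digests and headline metrics, including
continuum–truth correlation when simulation truth is available.
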