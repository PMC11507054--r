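# slcontinuum

Malignant-continuum analysis of serrated-lesion single-cell RNA-seq.

Serrated colorectal lesions progress through recognisable pathological stages
— normal mucosa, hyperplastic polyp (HP), sessile serrated lesion (SSL), SSL
with dysplasia (SSLD), traditional serrated adenoma (TSA), carcinoma — but
individual lesions sit at different points along that road. This package
orders whole samples along a continuous malignancy axis from their epithelial
expression profiles, and provides the surrounding single-cell toolkit:
expression-based copy-number inference, control-matched gene-program scoring,
cell-cycle phase assignment, stage-wise composition testing, and a
negative-binomial simulator that plants a known continuum, copy-number
segments, and gene programs so every method can be tested against ground
truth.

## The continuum method

For each non-normal sample, the malignant epithelial subtype's cells are
compared against the pooled subtype cells of the normal samples with a
two-part (hurdle) test: a two-proportion z-test on detection rates combined
with a Welch t-test on expression among expressing cells (Fisher's method,
χ² with 4 df). This yields a per-sample vector of log2 fold changes
`log2((mean(expm1(target)) + 1) / (mean(expm1(ref)) + 1))` and BH-adjusted
p-values. Genes significant (`p_adj < 0.05`) in at least two samples enter an
unscaled PCA of the samples-by-genes log2FC matrix; a Hastie–Stuetzle
principal curve fitted in the PC1/PC2 plane orders the samples, with
positions rescaled to [0, 1] and oriented from the earliest to the latest
pathological stage present. Spearman correlation of each gene's log2FC with
the continuum axis then yields gene trends.

## Worked example

Simulate the default study-scale cohort (12 samples across six stages, 150
cells each, 2000 genes of which 200 carry planted continuum slopes), then
recover the continuum:

```r
library(slcontinuum)

sim <- simulate_dataset(sim_config(seed = 1))
sim$dataset
#> <count_dataset> 1800 cells x 2000 genes
#>   samples: 12  stages: normal=300 HP=300 SSL=450 SSLD=150 TSA=300 tumor=300
#>   cell types: SLC1

norm <- normalize_counts(sim$dataset)
mc <- malignant_continuum(norm, "SLC1", axis = "position")
mc
#> <malignant_continuum> 10 samples, 206 selected genes, axis position
#> <continuum_fit> 10 samples ordered along the malignant continuum (converged, 4 iter)
#> # A tibble: 10 x 3
#>   sample_id stage position
#>   <chr>     <chr>    <dbl>
#> 1 HP_1      HP       0
#> 2 HP_2      HP       0.116
#> 3 SSL_1     SSL      0.225
#> 4 SSL_2     SSL      0.336
#> 5 SSL_3     SSL      0.460
#> 6 SSLD_1    SSLD     0.562
#> # i 4 more rows
```

The recovered ordering matches the planted progression exactly (Spearman
|rho| = 1 against the simulator's latent scores), and 200 of the 206 selected
genes — i.e. the 200 planted continuum genes — show significant trends along
the recovered axis:

```r
dplyr::arrange(mc$trends, p_adj, gene) |> head(3)
#> # A tibble: 3 x 6
#>   gene   spearman_rho p_value p_adj n_samples degenerate
#>   <chr>         <dbl>   <dbl> <dbl>     <int> <lgl>
#> 1 g00004        0.964       0     0        10 FALSE
#> 2 g00006        0.976       0     0        10 FALSE
#> 3 g00015        0.988       0     0        10 FALSE
```

Copy-number inference finds a planted chromosome-7p gain (copy ratio 1.5) in
tumor cells and nowhere else:

```r
sim <- simulate_dataset(sim_config(
  n_samples_per_stage = c(normal = 2L, tumor = 1L),
  n_cells_per_sample = 150L, n_genes = 2000L, n_continuum_genes = 0L,
  cnv_segments = list(list(arm = "7p", copy_ratio = 1.5, stages = "tumor")),
  seed = 1))
norm <- normalize_counts(sim$dataset)
ref <- cells_matching(norm$cells, stage = "normal")
prof <- smooth_by_position(relative_expression(norm, ref), window = 101)
ev <- arm_events(prof)
ev[ev$arm == "7p", ]
#> # A tibble: 3 x 6
#>   sample_id stage  arm   n_genes pct_gain pct_loss
#>   <chr>     <chr>  <chr>   <int>    <dbl>    <dbl>
#> 1 normal_1  normal 7p         38        0        0
#> 2 normal_2  normal 7p         38        0        0
#> 3 tumor_1   tumor  7p         38      100        0
```

`run_pipeline()` chains simulate → qc → composition → cnv → score →
continuum from a single YAML config (see
`system.file("extdata", "demo_run.yaml", package = "slcontinuum")`) and
writes provenance-headed TSVs plus a `report.json` whose digests are
byte-identical across re-runs with the same config and seed. A thin CLI
wrapper lives at `inst/cli/slcontinuum.R`.

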