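#' Reference-centered relative expression
#'
#' First step of expression-based CNV inference: subtract, per gene, the mean
#' normalized expression of a reference cell population (normal epithelial
#' cells from normal samples), then clip to `±cap` to bound the influence of
#' outlier genes. The reference's own centered values average to zero, so any
#' coherent regional deviation in other cells reflects copy-number-like
#' dosage.
#'
#' @param norm A [normalize_counts()] result.
#' @param reference_cells Character vector of reference barcodes.
#' @param cap Clipping bound (default 3).
#' @return Object of class `cnv_centered`: dense cells-by-genes matrix
#'   `values` plus `cells`, `genes`, `cap`, `reference_cells`.
#' @export
relative_expression <- function(norm, reference_cells, cap = 3) {
  stopifnot(inherits(norm, "normalized_matrix"))
  reference_cells <- intersect(reference_cells, norm$cells$barcode)
  if (!length(reference_cells)) abort("reference cell set is empty")
  assert_scalar_number(cap, "cap", lower = 1e-12)
  ref_mean <- Matrix::colMeans(norm$values[reference_cells, , drop = FALSE])
  values <- sweep(as.matrix(norm$values), 2, ref_mean, `-`)
  values[values > cap] <- cap
  values[values < -cap] <- -cap
  structure(list(values = values, cells = norm$cells, genes = norm$genes,
                 cap = cap, reference_cells = reference_cells),
            class = "cnv_centered")
}

# smoothing operator for one chromosome: centered moving average with
# half-width shrinking symmetrically at the edges
smoother_matrix <- function(n, window) {
  h_max <- (window - 1L) %/% 2L
  i <- rep(seq_len(n), times = pmin(h_max, seq_len(n) - 1L, n - seq_len(n)) * 2L + 1L)
  h <- pmin(h_max, seq_len(n) - 1L, n - seq_len(n))
  j <- unlist(lapply(seq_len(n), function(k) (k - h[k]):(k + h[k])))
  w <- rep(1 / (2 * h + 1), times = 2 * h + 1)
  Matrix::sparseMatrix(i = j, j = i, x = w, dims = c(n, n))
}

#' Positional smoothing of centered expression
#'
#' Orders genes genomically (chromosome, then start) and replaces each gene's
#' centered value by a moving average over its `window` genomic neighbours on
#' the same chromosome; the window shrinks symmetrically at chromosome edges
#' and never crosses a chromosome boundary. Genes without a placed arm are
#' dropped with a warning.
#'
#' @param centered A [relative_expression()] result.
#' @param window Odd window width, at least 3 (default 101).
#' @return Object of class `cnv_profile`: `smoothed` (cells x genes, genomic
#'   gene order), `genes` (reordered annotation), `cells`, `window`, `cap`,
#'   `reference_cells`.
#' @export
smooth_by_position <- function(centered, window = 101) {
  stopifnot(inherits(centered, "cnv_centered"))
  if (window < 3 || window %% 2 == 0) abort("`window` must be an odd integer >= 3")
  genes <- centered$genes
  placed <- !is.na(genes$arm) & !is.na(genes$chromosome) & !is.na(genes$start)
  if (any(!placed)) {
    warn(sprintf("dropping %d unplaced gene(s) before smoothing", sum(!placed)))
  }
  genes <- genes[placed, ]
  ord <- order(suppressWarnings(as.integer(genes$chromosome)), genes$chromosome,
               genes$start)
  genes <- genes[ord, ]
  values <- centered$values[, which(placed)[ord], drop = FALSE]

  chrom <- genes$chromosome
  smoothed <- matrix(0, nrow(values), ncol(values),
                     dimnames = dimnames(values))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- smoother_matrix(length(idx), window)
    smoothed[, idx] <- as.matrix(values[, idx, drop = FALSE] %*% s)
  }
  structure(list(smoothed = smoothed, genes = genes, cells = centered$cells,
                 window = window, cap = centered$cap,
                 reference_cells = centered$reference_cells),
            class = "cnv_profile")
}

#' Per-cell CNV burden scores
#'
#' Summarises each cell's smoothed, reference-centered profile by its mean
#' squared deviation from neutrality: a nonnegative, gene-count-stable proxy
#' for copy-number burden. Zero exactly when the smoothed row is identically
#' zero.
#'
#' @param profile A [smooth_by_position()] result.
#' @return Tibble with `cell_id`, `sample_id`, `stage`, `cell_type`,
#'   `cnv_score`.
#' @export
cnv_score <- function(profile) {
  stopifnot(inherits(profile, "cnv_profile"))
  score <- rowMeans(profile$smoothed^2)
  cells <- profile$cells
  tibble(cell_id = cells$barcode, sample_id = cells$sample_id,
         stage = cells$stage, cell_type = cells$cell_type,
         cnv_score = unname(score))
}

#' Chromosome-arm gain/loss percentages per sample
#'
#' For every sample and arm, averages the smoothed profile over the sample's
#' non-reference cells (samples consisting entirely of reference cells use all
#' their cells, so normal samples still appear) and reports the percentage of
#' the arm's genes whose sample-mean smoothed value exceeds `gain_thr`
#' (gain) or falls below `-loss_thr` (loss).
#'
#' @param profile A [smooth_by_position()] result.
#' @param gain_thr,loss_thr Positive thresholds on the smoothed log scale
#'   (default 0.1 each).
#' @return Tibble with `sample_id`, `stage`, `arm`, `n_genes`, `pct_gain`,
#'   `pct_loss`. Arms with no genes are omitted.
#' @export
arm_events <- function(profile, gain_thr = 0.1, loss_thr = 0.1) {
  stopifnot(inherits(profile, "cnv_profile"))
  assert_scalar_number(gain_thr, "gain_thr", lower = 0)
  assert_scalar_number(loss_thr, "loss_thr", lower = 0)
  cells <- profile$cells
  samples <- distinct(cells, .data$sample_id, .data$stage)
  arm <- profile$genes$arm
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    sid <- samples$sample_id[i]
    own <- cells$barcode[cells$sample_id == sid]
    use <- setdiff(own, profile$reference_cells)
    if (!length(use)) use <- own
    gene_mean <- colMeans(profile$smoothed[use, , drop = FALSE])
    by_arm <- split(gene_mean, arm)
    tibble(
      sample_id = sid, stage = samples$stage[i],
      arm = names(by_arm),
      n_genes = unname(lengths(by_arm)),
      pct_gain = 100 * unname(vapply(by_arm, function(v) mean(v > gain_thr), 0)),
      pct_loss = 100 * unname(vapply(by_arm, function(v) mean(v < -loss_thr), 0))
    )
  })
  out <- bind_rows(rows)
  out$arm <- factor(out$arm, levels = arm_levels())
  arrange(out, .data$sample_id, .data$arm) %>%
    mutate(arm = as.character(.data$arm))
}

#' Kruskal-Wallis comparison of CNV scores across groups
#'
#' Tests whether per-cell CNV scores differ across pathological stages or
#' cell types, with tie correction.
#'
#' @param score_tbl Output of [cnv_score()].
#' @param group `"stage"` or `"cell_type"`, or any column of `score_tbl`.
#' @param merge_sl Merge serrated stages into "SL" before grouping (only
#'   meaningful for `group = "stage"`).
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `n_groups`.
#' @export
score_group_test <- function(score_tbl, group = c("stage", "cell_type"),
                             merge_sl = FALSE) {
  group <- match.arg(group)
  g <- score_tbl[[group]]
  if (merge_sl && group == "stage") g <- merge_sl_stages(g)
  g <- factor(g)
  if (nlevels(g) < 2) abort("need at least two groups for a Kruskal-Wallis test")
  ht <- kruskal.test(score_tbl$cnv_score, g)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, n_groups = nlevels(g))
}
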