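#' Per-sample cell-type composition
#'
#' Tabulates cell counts and within-sample proportions for every combination
#' of sample and cell type present anywhere in the dataset; types absent from
#' a sample get an explicit zero row so per-sample proportion vectors are
#' directly comparable.
#'
#' @param cells Cell metadata: data frame with `sample_id`, `stage`,
#'   `cell_type` (e.g. the `cells` element of a [count_dataset()]).
#' @return Tibble with columns `sample_id`, `stage`, `cell_type`, `n_cells`,
#'   `proportion`; proportions sum to 1 within each sample.
#' @export
proportions_by_sample <- function(cells) {
  cells <- as_tibble(cells)
  stopifnot(all(c("sample_id", "stage", "cell_type") %in% names(cells)))
  samples <- distinct(cells, .data$sample_id, .data$stage)
  types <- sort(unique(cells$cell_type))
  grid <- tidyr::crossing(samples, cell_type = types)
  counts <- cells %>% count(.data$sample_id, .data$cell_type, name = "n_cells")
  grid %>%
    left_join(counts, by = c("sample_id", "cell_type")) %>%
    mutate(n_cells = tidyr::replace_na(.data$n_cells, 0L)) %>%
    group_by(.data$sample_id) %>%
    mutate(proportion = .data$n_cells / sum(.data$n_cells)) %>%
    ungroup() %>%
    arrange(.data$sample_id, .data$cell_type)
}

# collapse the four serrated-lesion stages into one "SL" group
merge_sl_stages <- function(stage) {
  if_else(stage %in% c("HP", "SSL", "SSLD", "TSA"), "SL", stage)
}

#' Pairwise stage test of a cell type's per-sample proportions
#'
#' Two-sided Wilcoxon rank-sum test comparing the per-sample proportions of
#' one cell type between two pathological stages, with the significance-star
#' convention NS p > 0.05, `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#' Exact p-values are used for group sizes up to 10 (falling back to the
#' tie-corrected normal approximation when ties make the exact distribution
#' unavailable).
#'
#' @param prop_tbl Output of [proportions_by_sample()].
#' @param cell_type Cell type to test.
#' @param stage_a,stage_b Stage labels (after SL merging if `merge_sl`).
#' @param merge_sl Merge HP/SSL/SSLD/TSA into a single "SL" group first.
#' @return One-row tibble: `cell_type`, `stage_a`, `stage_b`, `n_a`, `n_b`,
#'   `statistic`, `p_value`, `star`, `testable`. Groups with fewer than two
#'   samples are flagged `testable = FALSE` with NA statistic/p-value rather
#'   than raising an error.
#' @export
pairwise_stage_test <- function(prop_tbl, cell_type, stage_a, stage_b,
                                merge_sl = FALSE) {
  tbl <- prop_tbl
  if (merge_sl) tbl <- mutate(tbl, stage = merge_sl_stages(.data$stage))
  ct <- cell_type
  x <- tbl$proportion[tbl$cell_type == ct & tbl$stage == stage_a]
  y <- tbl$proportion[tbl$cell_type == ct & tbl$stage == stage_b]
  if (length(x) < 2 || length(y) < 2) {
    return(tibble(cell_type = ct, stage_a = stage_a, stage_b = stage_b,
                  n_a = length(x), n_b = length(y),
                  statistic = NA_real_, p_value = NA_real_,
                  star = NA_character_, testable = FALSE))
  }
  exact <- max(length(x), length(y)) <= 10
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = FALSE)
  )
  p <- ht$p.value
  # complete ties degenerate the normal approximation; no evidence -> p = 1
  if (is.nan(p)) p <- 1
  tibble(cell_type = ct, stage_a = stage_a, stage_b = stage_b,
         n_a = length(x), n_b = length(y),
         statistic = unname(ht$statistic), p_value = p,
         star = p_stars(p), testable = TRUE)
}

#' All pairwise stage tests for every cell type
#'
#' Convenience wrapper running [pairwise_stage_test()] over a list of stage
#' pairs and all cell types, optionally BH-adjusting p-values across cell
#' types within each stage pair.
#'
#' @param prop_tbl Output of [proportions_by_sample()].
#' @param pairs List of length-2 character vectors of stage labels, or a
#'   string like `"normal:SL,SL:tumor"`.
#' @param merge_sl Merge serrated stages into "SL".
#' @param adjust Apply BH correction across cell types (default FALSE; the
#'   conventional per-figure stars are unadjusted).
#' @return Tibble of test rows; when `adjust = TRUE` a `p_adj` column and
#'   stars mapped from it.
#' @export
composition_tests <- function(prop_tbl, pairs, merge_sl = FALSE, adjust = FALSE) {
  if (is.character(pairs) && length(pairs) == 1) {
    pairs <- lapply(strsplit(strsplit(pairs, ",", fixed = TRUE)[[1]], ":", fixed = TRUE),
                    identity)
  }
  types <- sort(unique(prop_tbl$cell_type))
  out <- bind_rows(lapply(pairs, function(pr) {
    bind_rows(lapply(types, function(ct) {
      pairwise_stage_test(prop_tbl, ct, pr[[1]], pr[[2]], merge_sl = merge_sl)
    }))
  }))
  if (adjust) {
    out <- out %>%
      group_by(.data$stage_a, .data$stage_b) %>%
      mutate(p_adj = p.adjust(.data$p_value, "BH"),
             star = p_stars(.data$p_adj)) %>%
      ungroup()
  }
  out
}
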