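#' Control-matched gene-set module score
#'
#' Scores each cell for a gene program as the mean normalized expression of
#' the set genes minus the mean over expression-matched control genes. Genes
#' are binned into `n_bins` groups by their average expression across cells;
#' each set gene contributes `n_ctrl` control genes sampled from its bin
#' (excluding set genes; without replacement while the bin lasts, with
#' replacement once exhausted). The control subtraction cancels cell-wide
#' shifts, so the score reflects program-specific activity.
#'
#' @param norm A [normalize_counts()] result.
#' @param gene_set Character vector of gene ids or names; genes missing from
#'   the matrix are dropped with a warning, and an error is raised if none
#'   remain.
#' @param program Name recorded in the output (default "module").
#' @param n_bins Number of average-expression bins (>= 2, default 25).
#' @param n_ctrl Control genes per set gene (default 100).
#' @param seed Seed for control sampling; scores are deterministic given it.
#' @return Tibble with `cell_id`, `program`, `score`; scoring parameters kept
#'   in `attr(, "params")`.
#' @export
module_score <- function(norm, gene_set, program = "module",
                         n_bins = 25, n_ctrl = 100, seed = 0L) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (n_bins < 2) abort("n_bins must be >= 2")
  ids <- norm$genes$gene_id
  hits <- ids %in% gene_set | norm$genes$gene_name %in% gene_set
  if (!any(hits)) abort(paste0("no gene of program '", program, "' is present in the matrix"))
  n_miss <- length(unique(gene_set)) - sum(hits)
  if (n_miss > 0) {
    warn(sprintf("program '%s': %d gene(s) absent from the matrix were dropped",
                 program, n_miss))
  }
  set_idx <- which(hits)

  avg <- Matrix::colMeans(norm$values)
  bin <- dplyr::ntile(rank(avg, ties.method = "first"), n_bins)

  ctrl_idx <- with_seed(derive_seed(seed, paste0("module:", program)), {
    unlist(lapply(set_idx, function(g) {
      pool <- setdiff(which(bin == bin[g]), set_idx)
      if (!length(pool)) {
        warn(sprintf("program '%s': bin of gene %s has no control genes; using all non-set genes",
                     program, ids[g]))
        pool <- setdiff(seq_along(ids), set_idx)
      }
      if (length(pool) >= n_ctrl) sample(pool, n_ctrl)
      else sample(pool, n_ctrl, replace = TRUE)
    }))
  })

  set_mean <- Matrix::rowMeans(norm$values[, set_idx, drop = FALSE])
  mult <- tabulate(ctrl_idx, nbins = length(ids))
  used <- which(mult > 0)
  ctrl_mean <- as.numeric(norm$values[, used, drop = FALSE] %*% mult[used]) /
    sum(mult)
  out <- tibble(cell_id = norm$cells$barcode, program = program,
                score = unname(set_mean - ctrl_mean))
  attr(out, "params") <- list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  out
}

#' Score several programs from a gene-set collection
#'
#' @param norm A [normalize_counts()] result.
#' @param sets Gene-set tibble as from [read_gmt()], or a named list of gene
#'   vectors.
#' @param ... Passed to [module_score()].
#' @return Row-bound module score tibble, one block per program.
#' @export
module_scores <- function(norm, sets, ...) {
  if (is.data.frame(sets)) {
    sets <- setNames(sets$genes, sets$set)
  }
  bind_rows(lapply(names(sets), function(nm) {
    module_score(norm, sets[[nm]], program = nm, ...)
  }))
}

#' Cell-cycle phase assignment from S and G2M module scores
#'
#' A cell is G1 when both scores are nonpositive; otherwise it takes the
#' phase of the larger score (ties resolved to S).
#'
#' @param score_tbl Module score tibble containing the two cell-cycle
#'   programs.
#' @param s_program,g2m_program Program names holding the S-phase and
#'   G2M-phase scores.
#' @return Tibble with `cell_id`, `s_score`, `g2m_score`, `phase` in
#'   `c("G1", "S", "G2M")`.
#' @export
assign_phase <- function(score_tbl, s_program = "S", g2m_program = "G2M") {
  wide <- score_tbl %>%
    filter(.data$program %in% c(s_program, g2m_program)) %>%
    tidyr::pivot_wider(id_cols = "cell_id", names_from = "program",
                       values_from = "score")
  if (!all(c(s_program, g2m_program) %in% names(wide)) ||
      anyNA(wide[[s_program]]) || anyNA(wide[[g2m_program]])) {
    abort("every cell needs both an S and a G2M score")
  }
  s <- wide[[s_program]]
  g2m <- wide[[g2m_program]]
  tibble(
    cell_id = wide$cell_id, s_score = s, g2m_score = g2m,
    phase = if_else(s <= 0 & g2m <= 0, "G1", if_else(s >= g2m, "S", "G2M"))
  )
}

#' Group summary and Kruskal-Wallis test of module scores
#'
#' Summarises one program's scores by externally supplied group labels
#' (e.g. trajectory states or pathological stages) and tests for any
#' group difference.
#'
#' @param score_tbl Module score tibble (one program, or filter first).
#' @param groups Data frame with `cell_id` and a grouping column.
#' @param group_col Name of the grouping column in `groups`.
#' @return List with `summary` (per-group n, median, q1, q3) and `test`
#'   (one-row tibble with Kruskal-Wallis H, df, p_value).
#' @export
score_by_group <- function(score_tbl, groups, group_col = "group") {
  if (length(unique(score_tbl$program)) > 1) {
    abort("score_by_group expects a single program; filter the score table first")
  }
  joined <- left_join(score_tbl, groups, by = "cell_id")
  g <- factor(joined[[group_col]])
  if (nlevels(g) < 2) abort("need at least two groups")
  ht <- kruskal.test(joined$score, g)
  summary <- joined %>%
    group_by(group = .data[[group_col]]) %>%
    summarise(n = dplyr::n(), median = median(.data$score),
              q1 = quantile(.data$score, 0.25), q3 = quantile(.data$score, 0.75),
              .groups = "drop")
  list(summary = summary,
       test = tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                     p_value = ht$p.value))
}
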