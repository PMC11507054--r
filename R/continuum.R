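#' Two-part (hurdle) differential expression between two cell groups
#'
#' Single-cell expression is zero-inflated, so a difference can show up in how
#' often a gene is detected, in how strongly it is expressed when detected, or
#' both. This test combines (a) a two-proportion z-test on the expressed-cell
#' fractions and (b) a Welch t-test on normalized expression among expressing
#' cells, via Fisher's method (chi-squared, df 4; df 2 when only one part is
#' defined). The fold change is computed on de-logged group means with a
#' pseudocount of 1: `log2fc = log2((mean(expm1(target)) + 1) /
#' (mean(expm1(ref)) + 1))`.
#'
#' @param norm A [normalize_counts()] result.
#' @param target_cells,reference_cells Barcode vectors of the two groups.
#' @param min_cells Minimum group size (default 10); smaller groups return
#'   NULL (the caller flags the sample as unprofiled).
#' @param min_pct Genes detected in fewer than this fraction of cells in both
#'   groups are skipped (default 0.05).
#' @param method `"hurdle"` (default) or `"wilcox"` (rank-sum on all cells,
#'   a robust fallback).
#' @return Tibble with one row per tested gene: `gene`, `log2fc`, `p_value`,
#'   `pct_expr_target`, `pct_expr_ref`, `n_target_cells`, `n_ref_cells`;
#'   or NULL when either group is below `min_cells`.
#' @export
hurdle_de <- function(norm, target_cells, reference_cells,
                      min_cells = 10, min_pct = 0.05,
                      method = c("hurdle", "wilcox")) {
  stopifnot(inherits(norm, "normalized_matrix"))
  method <- match.arg(method)
  Xt <- norm$values[norm$cells$barcode %in% target_cells, , drop = FALSE]
  Xr <- norm$values[norm$cells$barcode %in% reference_cells, , drop = FALSE]
  nt <- nrow(Xt); nr <- nrow(Xr)
  if (nt < min_cells || nr < min_cells) return(NULL)

  nzt <- col_nnz(Xt); nzr <- col_nnz(Xr)
  pt_ <- nzt / nt; pr_ <- nzr / nr
  tested <- pt_ >= min_pct | pr_ >= min_pct
  if (!any(tested)) return(NULL)

  mean_t <- Matrix::colSums(expm1(Xt)) / nt
  mean_r <- Matrix::colSums(expm1(Xr)) / nr
  log2fc <- log2((mean_t + 1) / (mean_r + 1))

  p <- if (method == "hurdle") {
    hurdle_p(Xt, Xr, nzt, nzr)
  } else {
    vapply(seq_len(ncol(Xt)), function(j) {
      suppressWarnings(wilcox.test(Xt[, j], Xr[, j], exact = FALSE)$p.value)
    }, 0)
  }

  tibble(
    gene = colnames(norm$values),
    log2fc = unname(log2fc), p_value = unname(p),
    pct_expr_target = unname(pt_), pct_expr_ref = unname(pr_),
    n_target_cells = nt, n_ref_cells = nr
  )[tested, ]
}

# Fisher-combined two-part p-values, fully vectorised over genes.
hurdle_p <- function(Xt, Xr, nzt, nzr) {
  nt <- nrow(Xt); nr <- nrow(Xr)

  # part 1: detection-rate two-proportion z-test (pooled SE, two-sided);
  # undefined when the pooled rate is 0 or 1
  phat <- (nzt + nzr) / (nt + nr)
  se <- sqrt(phat * (1 - phat) * (1 / nt + 1 / nr))
  z <- (nzt / nt - nzr / nr) / se
  p_det <- 2 * pnorm(-abs(z))
  p_det[!is.finite(p_det)] <- NA_real_

  # part 2: Welch t-test on expression among expressing cells, from
  # sparse column sums (needs >= 2 expressing cells per group and variance)
  st <- Matrix::colSums(Xt); st2 <- Matrix::colSums(Xt^2)
  sr <- Matrix::colSums(Xr); sr2 <- Matrix::colSums(Xr^2)
  mt <- ifelse(nzt > 0, st / nzt, NA_real_)
  mr <- ifelse(nzr > 0, sr / nzr, NA_real_)
  vt <- ifelse(nzt > 1, pmax(st2 - nzt * mt^2, 0) / (nzt - 1), NA_real_)
  vr <- ifelse(nzr > 1, pmax(sr2 - nzr * mr^2, 0) / (nzr - 1), NA_real_)
  a <- vt / nzt; b <- vr / nzr
  tstat <- (mt - mr) / sqrt(a + b)
  df <- (a + b)^2 / (a^2 / (nzt - 1) + b^2 / (nzr - 1))
  p_expr <- 2 * pt(-abs(tstat), df)
  p_expr[!is.finite(p_expr)] <- NA_real_

  both <- !is.na(p_det) & !is.na(p_expr)
  one <- xor(is.na(p_det), is.na(p_expr))
  p <- rep(NA_real_, length(p_det))
  if (any(both)) {
    stat <- -2 * (log(pmax(p_det[both], 1e-300)) + log(pmax(p_expr[both], 1e-300)))
    p[both] <- pchisq(stat, df = 4, lower.tail = FALSE)
  }
  p[one] <- ifelse(is.na(p_det[one]), p_expr[one], p_det[one])
  p
}

#' Per-sample log2FC profiles of a target subtype against a normal reference
#'
#' Pools the target subtype's cells from all reference-stage samples into one
#' reference population, then runs [hurdle_de()] of each non-reference
#' sample's target-subtype cells against it, BH-adjusting p-values within each
#' sample across genes. Samples with fewer than `min_cells` target cells are
#' skipped with a message (flagged unprofiled, not an error).
#'
#' @param norm A [normalize_counts()] result.
#' @param target_subtype Cell type to profile (e.g. "SLC1").
#' @param reference_stage Stage providing reference cells (default "normal").
#' @param min_cells,min_pct,method Passed to [hurdle_de()].
#' @return Tibble: `sample_id`, `stage`, `gene`, `log2fc`, `p_value`, `p_adj`,
#'   `pct_expr_target`, `pct_expr_ref`, `n_target_cells`, `n_ref_cells`.
#' @export
profile_all_samples <- function(norm, target_subtype, reference_stage = "normal",
                                min_cells = 10, min_pct = 0.05,
                                method = c("hurdle", "wilcox")) {
  method <- match.arg(method)
  meta <- norm$cells
  ref <- cells_matching(meta, stage = reference_stage, cell_type = target_subtype)
  if (!length(ref)) {
    abort(paste0("no reference cells: no '", target_subtype, "' cells in stage '",
                 reference_stage, "'"))
  }
  samples <- distinct(filter(meta, .data$stage != reference_stage),
                      .data$sample_id, .data$stage)
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    sid <- samples$sample_id[i]
    tgt <- meta$barcode[meta$sample_id == sid & meta$cell_type == target_subtype]
    de <- hurdle_de(norm, tgt, ref, min_cells = min_cells, min_pct = min_pct,
                    method = method)
    if (is.null(de)) {
      inform(paste0("sample ", sid, " skipped: fewer than ", min_cells,
                    " target-subtype cells"))
      return(NULL)
    }
    de$p_adj <- p.adjust(de$p_value, method = "BH")
    mutate(de, sample_id = sid, stage = samples$stage[i], .before = 1)
  })
  out <- bind_rows(rows)
  if (!nrow(out)) abort("no sample could be profiled")
  out
}

#' Select continuum genes from per-sample DE profiles
#'
#' A gene enters the continuum analysis when it is significantly
#' differentially expressed (BH-adjusted p below `alpha`) in at least
#' `min_samples` samples.
#'
#' @param profile Output of [profile_all_samples()].
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_samples Minimum number of samples (default 2).
#' @return Character vector of gene ids.
#' @export
select_continuum_genes <- function(profile, alpha = 0.05, min_samples = 2) {
  assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1)
  assert_scalar_number(min_samples, "min_samples", lower = 1)
  hits <- profile %>%
    filter(!is.na(.data$p_adj), .data$p_adj < alpha | alpha >= 1) %>%
    count(.data$gene) %>%
    filter(.data$n >= min_samples)
  if (!nrow(hits)) {
    abort("no gene passes the selection rule; consider raising `alpha` or lowering `min_samples`")
  }
  sort(hits$gene)
}

#' PCA of the samples-by-genes log2FC matrix
#'
#' Builds the samples x selected-genes matrix of log2 fold changes (entries a
#' sample never tested are imputed as 0, i.e. "no evidence of change"; the
#' imputation count is messaged), column-centers it, and runs an unscaled PCA.
#' Each component's loading vector is oriented so that its largest-magnitude
#' loading is positive, making the sign deterministic.
#'
#' @param profile Output of [profile_all_samples()].
#' @param genes Genes to use (e.g. from [select_continuum_genes()]).
#' @return Object of class `continuum_pca`: `scores` tibble (`sample_id`,
#'   `stage`, `PC1`, `PC2`), `explained_variance` (proportions for PC1/PC2),
#'   `rotation`, `sdev`, `n_imputed`, `genes`.
#' @export
continuum_pca <- function(profile, genes) {
  sub <- filter(profile, .data$gene %in% genes)
  wide <- sub %>%
    select("sample_id", "gene", "log2fc") %>%
    tidyr::pivot_wider(names_from = "gene", values_from = "log2fc")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  if (nrow(m) < 3) abort("continuum PCA needs at least 3 profiled samples")
  if (ncol(m) < 2) abort("continuum PCA needs at least 2 selected genes")
  n_imp <- sum(is.na(m))
  if (n_imp > 0) {
    inform(sprintf("imputing %d untested (sample, gene) log2fc entries as 0", n_imp))
    m[is.na(m)] <- 0
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  if (ncol(pc$x) < 2) abort("log2FC matrix has rank < 2; cannot embed samples in a plane")
  # deterministic sign: largest-|loading| entry of each PC positive
  for (k in 1:2) {
    l <- pc$rotation[, k]
    if (l[which.max(abs(l))] < 0) {
      pc$rotation[, k] <- -l
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  stages <- distinct(profile, .data$sample_id, .data$stage)
  scores <- tibble(sample_id = rownames(pc$x),
                   PC1 = pc$x[, 1], PC2 = pc$x[, 2]) %>%
    left_join(stages, by = "sample_id") %>%
    select("sample_id", "stage", "PC1", "PC2")
  structure(list(scores = scores, explained_variance = ev[1:2],
                 rotation = pc$rotation[, 1:2, drop = FALSE],
                 sdev = pc$sdev, n_imputed = n_imp, genes = colnames(m)),
            class = "continuum_pca")
}

#' @exportS3Method base::print
print.continuum_pca <- function(x, ...) {
  cat(sprintf("<continuum_pca> %d samples x %d genes; PC1 %.1f%%, PC2 %.1f%% variance\n",
              nrow(x$scores), length(x$genes),
              100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  invisible(x)
}

# ---- principal curve -------------------------------------------------------

# smoother for one coordinate against arc length; falls back to an exact
# linear fit when the spline is unidentifiable or the data are exactly linear
fit_coord_smoother <- function(lambda, y) {
  lin <- lm(y ~ lambda)
  if (sd(y) < 1e-12 || length(unique(lambda)) < 5 ||
      sum(stats::residuals(lin)^2) < 1e-18 * max(1, sum(y^2))) {
    co <- coef(lin)
    return(function(l) co[1] + co[2] * l)
  }
  ss <- tryCatch(suppressWarnings(smooth.spline(lambda, y, cv = FALSE)),
                 error = function(e) NULL)
  if (is.null(ss)) {
    co <- coef(lin)
    return(function(l) co[1] + co[2] * l)
  }
  function(l) predict(ss, l)$y
}

# project points (n x 2) onto a polyline (m x 2); returns arc-length position
# and squared distance of the orthogonal foot
project_polyline <- function(pts, poly) {
  seg_start <- poly[-nrow(poly), , drop = FALSE]
  seg_vec <- poly[-1, , drop = FALSE] - seg_start
  seg_len2 <- rowSums(seg_vec^2)
  seg_len2[seg_len2 == 0] <- 1e-300
  cum <- c(0, cumsum(sqrt(rowSums(seg_vec^2))))
  lambda <- numeric(nrow(pts)); dist2 <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d <- sweep(seg_start, 2, pts[i, ], `-`)
    t <- pmin(1, pmax(0, -(d[, 1] * seg_vec[, 1] + d[, 2] * seg_vec[, 2]) / seg_len2))
    foot <- seg_start + seg_vec * t
    dd <- rowSums(sweep(foot, 2, pts[i, ], `-`)^2)
    j <- which.min(dd)
    dist2[i] <- dd[j]
    lambda[i] <- cum[j] + t[j] * sqrt(seg_len2[j])
  }
  list(lambda = lambda, dist2 = dist2)
}

#' Principal-curve ordering of samples in the PC1-PC2 plane
#'
#' Fits a Hastie-Stuetzle principal curve: starting from the PC1 projection,
#' alternate (i) smoothing each coordinate against current arc-length
#' positions with a cross-validated smoothing spline and (ii) re-projecting
#' the samples orthogonally onto the refitted curve, until the mean projection
#' displacement falls below `tol` or `max_iter` is reached (non-convergence
#' returns the last iterate with `converged = FALSE`). Arc-length positions
#' are rescaled to `[0, 1]` and oriented so that the least-progressed stage
#' present sits, on average, below the most-progressed one — the continuum
#' runs from normal-like to cancer-like.
#'
#' @param x A [continuum_pca()] result, or a data frame with `sample_id`,
#'   `PC1`, `PC2` and optionally `stage`.
#' @param stages Optional named stage vector (sample_id -> stage) overriding
#'   the `stage` column; used only for orientation.
#' @param tol Convergence tolerance on mean projection displacement
#'   (default 1e-4, on the PC coordinate scale).
#' @param max_iter Maximum iterations (default 30).
#' @param grid_n Number of curve evaluation points (default 200).
#' @return Object of class `continuum_fit`: `positions` tibble (`sample_id`,
#'   `stage`, `PC1`, `PC2`, `lambda`, `position` in `[0, 1]`), `curve` tibble
#'   of polyline points, `converged`, `n_iter`, `orientation_anchor`, and the
#'   PCA's `explained_variance` when available.
#' @export
fit_principal_curve <- function(x, stages = NULL, tol = 1e-4, max_iter = 30,
                                grid_n = 200) {
  ev <- NULL
  if (inherits(x, "continuum_pca")) {
    ev <- x$explained_variance
    df <- x$scores
  } else {
    df <- as_tibble(x)
  }
  if (nrow(df) < 4) abort("principal-curve fitting needs at least 4 samples")
  if (is.null(df$stage)) df$stage <- NA_character_
  pts <- as.matrix(df[, c("PC1", "PC2")])
  if (!is.null(stages)) {
    df$stage <- unname(stages[df$sample_id])
  }

  lambda <- pts[, 1] - min(pts[, 1])
  prev_foot <- pts
  converged <- FALSE
  iter <- 0L
  curve_pts <- NULL
  for (iter in seq_len(max_iter)) {
    f1 <- fit_coord_smoother(lambda, pts[, 1])
    f2 <- fit_coord_smoother(lambda, pts[, 2])
    grid <- seq(min(lambda), max(lambda), length.out = grid_n)
    curve_pts <- cbind(f1(grid), f2(grid))
    pr <- project_polyline(pts, curve_pts)
    lambda_new <- pr$lambda
    if (diff(range(lambda_new)) < 1e-12) {
      # degenerate collapse; keep previous parameterisation
      break
    }
    foot <- cbind(stats::approx(c(0, cumsum(sqrt(rowSums(diff(curve_pts)^2)))),
                                curve_pts[, 1], xout = pr$lambda, rule = 2)$y,
                  stats::approx(c(0, cumsum(sqrt(rowSums(diff(curve_pts)^2)))),
                                curve_pts[, 2], xout = pr$lambda, rule = 2)$y)
    disp <- mean(sqrt(rowSums((foot - prev_foot)^2)))
    prev_foot <- foot
    lambda <- lambda_new
    if (disp < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("principal curve did not converge in %d iterations; returning last iterate",
                 max_iter))
  }

  position <- (lambda - min(lambda)) / (max(lambda) - min(lambda))

  anchor <- NA_character_
  if (!is.null(df$stage) && !all(is.na(df$stage))) {
    present <- intersect(stage_levels(), unique(df$stage))
    if (length(present) >= 2) {
      lo <- present[1]; hi <- present[length(present)]
      anchor <- paste0(lo, "->", hi)
      if (mean(position[df$stage == lo]) > mean(position[df$stage == hi])) {
        position <- 1 - position
        lambda <- max(lambda) - lambda
        curve_pts <- curve_pts[rev(seq_len(nrow(curve_pts))), , drop = FALSE]
      }
    }
  }

  cum <- c(0, cumsum(sqrt(rowSums(diff(curve_pts)^2))))
  positions <- df %>%
    mutate(lambda = lambda, position = position) %>%
    arrange(.data$position)
  structure(list(
    positions = positions,
    curve = tibble(lambda = cum, PC1 = curve_pts[, 1], PC2 = curve_pts[, 2]),
    converged = converged, n_iter = iter,
    orientation_anchor = anchor,
    explained_variance = ev
  ), class = "continuum_fit")
}

#' @exportS3Method base::print
print.continuum_fit <- function(x, ...) {
  cat(sprintf("<continuum_fit> %d samples ordered along the malignant continuum (%s, %d iter)\n",
              nrow(x$positions),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  print(select(x$positions, "sample_id", "stage", "position"), n = 6)
  invisible(x)
}

#' Spearman gene trends along the continuum axis
#'
#' For each gene, correlates its per-sample log2 fold changes with a
#' continuum axis — PC2 by default, or the principal-curve position — using
#' Spearman's rank correlation, with BH adjustment across genes. Genes whose
#' log2fc vector is constant get an NA correlation and are flagged
#' `degenerate`.
#'
#' @param profile Output of [profile_all_samples()].
#' @param scores A [continuum_pca()] or [fit_principal_curve()] result
#'   supplying per-sample axis values.
#' @param axis `"PC2"` (default) or `"position"`.
#' @param genes Genes to test (default: all genes in `profile`).
#' @return Tibble with `gene`, `spearman_rho`, `p_value`, `p_adj`,
#'   `n_samples`, `degenerate`.
#' @export
gene_trends <- function(profile, scores, axis = c("PC2", "position"),
                        genes = NULL) {
  axis <- match.arg(axis)
  ax_tbl <- if (inherits(scores, "continuum_pca")) scores$scores
            else if (inherits(scores, "continuum_fit")) scores$positions
            else as_tibble(scores)
  if (!axis %in% names(ax_tbl)) {
    abort(paste0("axis '", axis, "' not available in the supplied scores"))
  }
  ax <- setNames(ax_tbl[[axis]], ax_tbl$sample_id)
  sub <- filter(profile, .data$sample_id %in% names(ax))
  if (!is.null(genes)) sub <- filter(sub, .data$gene %in% genes)
  if (length(unique(sub$sample_id)) < 4) {
    abort("gene trends need at least 4 profiled samples")
  }
  rows <- sub %>%
    group_by(.data$gene) %>%
    summarise(res = list({
      v <- .data$log2fc
      a <- ax[.data$sample_id]
      if (sd(v) < 1e-15 || length(v) < 4) {
        tibble(spearman_rho = NA_real_, p_value = NA_real_,
               n_samples = length(v), degenerate = TRUE)
      } else {
        ht <- suppressWarnings(cor.test(v, a, method = "spearman"))
        tibble(spearman_rho = unname(ht$estimate), p_value = ht$p.value,
               n_samples = length(v), degenerate = FALSE)
      }
    }), .groups = "drop") %>%
    tidyr::unnest("res")
  rows$p_adj <- p.adjust(rows$p_value, method = "BH")
  select(rows, "gene", "spearman_rho", "p_value", "p_adj", "n_samples",
         "degenerate")
}

#' One-vs-rest marker genes per cell type
#'
#' Runs [hurdle_de()] of each cell type against all remaining cells and
#' reports, per type, the `top_n` significant genes (BH-adjusted p below
#' `alpha`) ranked by decreasing log2 fold change. Types below `min_cells`
#' are skipped with a warning.
#'
#' @param norm A [normalize_counts()] result.
#' @param top_n Markers per type (default 5).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param min_cells,min_pct Passed to [hurdle_de()].
#' @return Tibble `cell_type`, `rank`, `gene`, `log2fc`, `p_value`, `p_adj`.
#' @export
one_vs_rest_markers <- function(norm, top_n = 5, alpha = 0.05,
                                min_cells = 10, min_pct = 0.05) {
  types <- sort(unique(norm$cells$cell_type))
  if (length(types) < 2) abort("one-vs-rest markers need at least 2 cell types")
  if (top_n == 0) {
    return(tibble(cell_type = character(), rank = integer(), gene = character(),
                  log2fc = numeric(), p_value = numeric(), p_adj = numeric()))
  }
  bind_rows(lapply(types, function(ct) {
    tgt <- norm$cells$barcode[norm$cells$cell_type == ct]
    rest <- setdiff(norm$cells$barcode, tgt)
    de <- hurdle_de(norm, tgt, rest, min_cells = min_cells, min_pct = min_pct)
    if (is.null(de)) {
      warn(paste0("cell type ", ct, " skipped (fewer than ", min_cells, " cells)"))
      return(NULL)
    }
    de$p_adj <- p.adjust(de$p_value, "BH")
    de %>%
      filter(!is.na(.data$p_adj), .data$p_adj < alpha, .data$log2fc > 0) %>%
      arrange(dplyr::desc(.data$log2fc)) %>%
      utils::head(top_n) %>%
      mutate(cell_type = ct, rank = row_number()) %>%
      select("cell_type", "rank", "gene", "log2fc", "p_value", "p_adj")
  }))
}

#' End-to-end malignant-continuum analysis
#'
#' Convenience wrapper chaining [profile_all_samples()],
#' [select_continuum_genes()], [continuum_pca()], [fit_principal_curve()] and
#' [gene_trends()].
#'
#' @param norm A [normalize_counts()] result.
#' @param target_subtype Malignant subtype to profile (e.g. "SLC1").
#' @param reference_stage Reference stage (default "normal").
#' @param alpha,min_samples Gene selection parameters.
#' @param axis Trend axis, `"PC2"` (default) or `"position"`.
#' @param ... Passed to [profile_all_samples()].
#' @return Object of class `malignant_continuum` with elements `profile`,
#'   `selected_genes`, `pca`, `fit`, `trends`.
#' @export
malignant_continuum <- function(norm, target_subtype,
                                reference_stage = "normal",
                                alpha = 0.05, min_samples = 2,
                                axis = c("PC2", "position"), ...) {
  axis <- match.arg(axis)
  profile <- profile_all_samples(norm, target_subtype,
                                 reference_stage = reference_stage, ...)
  selected <- select_continuum_genes(profile, alpha = alpha,
                                     min_samples = min_samples)
  pca <- continuum_pca(profile, selected)
  fit <- fit_principal_curve(pca)
  trends <- gene_trends(profile, if (axis == "PC2") pca else fit,
                        axis = axis, genes = selected)
  structure(list(profile = profile, selected_genes = selected, pca = pca,
                 fit = fit, trends = trends, axis = axis,
                 params = list(target_subtype = target_subtype,
                               reference_stage = reference_stage,
                               alpha = alpha, min_samples = min_samples)),
            class = "malignant_continuum")
}

#' @exportS3Method base::print
print.malignant_continuum <- function(x, ...) {
  cat(sprintf("<malignant_continuum> %d samples, %d selected genes, axis %s\n",
              nrow(x$fit$positions), length(x$selected_genes), x$axis))
  print(x$fit)
  invisible(x)
}
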