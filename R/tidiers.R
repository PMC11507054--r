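#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a continuum fit into one row per sample
#'
#' @param x A [fit_principal_curve()] result.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `stage`, `PC1`, `PC2`, `position`.
#' @export
tidy.continuum_fit <- function(x, ...) {
  select(x$positions, "sample_id", "stage", "PC1", "PC2", "position")
}

#' One-row summary of a continuum fit
#'
#' @param x A [fit_principal_curve()] result.
#' @param ... Unused.
#' @return Tibble with `n_samples`, `converged`, `n_iter`,
#'   `var_explained_pc1`, `var_explained_pc2`.
#' @export
glance.continuum_fit <- function(x, ...) {
  ev <- x$explained_variance %||% c(NA_real_, NA_real_)
  tibble(n_samples = nrow(x$positions), converged = x$converged,
         n_iter = x$n_iter,
         var_explained_pc1 = ev[1], var_explained_pc2 = ev[2])
}

#' @rdname tidy.continuum_fit
#' @export
tidy.malignant_continuum <- function(x, ...) tidy(x$fit, ...)

#' One-row summary of a full continuum analysis
#'
#' @param x A [malignant_continuum()] result.
#' @param ... Unused.
#' @return Tibble adding `n_selected_genes` and `n_trend_genes` (significant
#'   Spearman trends at BH 0.05) to [glance.continuum_fit()].
#' @export
glance.malignant_continuum <- function(x, ...) {
  g <- glance(x$fit)
  g$n_selected_genes <- length(x$selected_genes)
  g$n_trend_genes <- sum(x$trends$p_adj < 0.05, na.rm = TRUE)
  g
}
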