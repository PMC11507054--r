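#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_path geom_col
#'   geom_violin geom_boxplot geom_tile facet_wrap labs theme_minimal
#'   scale_fill_gradient2 element_text theme
NULL

#' @export
ggplot2::autoplot

#' Plot the malignant continuum in PC space
#'
#' Samples in the PC1-PC2 plane, coloured by stage, with the fitted principal
#' curve drawn through them.
#'
#' @param object A [fit_principal_curve()] or [malignant_continuum()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.continuum_fit <- function(object, ...) {
  ggplot(object$positions, aes(x = .data$PC1, y = .data$PC2)) +
    geom_path(data = object$curve, colour = "red", linewidth = 0.6) +
    geom_point(aes(colour = .data$stage), size = 2.5) +
    labs(title = "Malignant continuum",
         subtitle = "principal curve over per-sample log2FC principal components",
         colour = "stage") +
    theme_minimal()
}

#' @rdname autoplot.continuum_fit
#' @export
autoplot.malignant_continuum <- function(object, ...) autoplot(object$fit, ...)

#' Heatmap of chromosome-arm gain/loss percentages
#'
#' @param arm_tbl Output of [arm_events()].
#' @return A ggplot object: samples by arms, gain percentage minus loss
#'   percentage as a diverging fill.
#' @export
plot_arm_events <- function(arm_tbl) {
  arm_tbl %>%
    mutate(arm = factor(.data$arm, levels = arm_levels()),
           net = .data$pct_gain - .data$pct_loss) %>%
    ggplot(aes(x = .data$arm, y = .data$sample_id, fill = .data$net)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         name = "% gain - % loss") +
    labs(x = "chromosome arm", y = NULL,
         title = "Arm-level gain/loss percentages") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 7))
}

#' Violin plot of per-cell CNV scores by group
#'
#' @param score_tbl Output of [cnv_score()].
#' @param group `"stage"` or `"cell_type"`.
#' @return A ggplot object.
#' @export
plot_cnv_scores <- function(score_tbl, group = c("stage", "cell_type")) {
  group <- match.arg(group)
  df <- score_tbl
  if (group == "stage") {
    df$stage <- factor(df$stage, levels = stage_levels())
  }
  ggplot(df, aes(x = .data[[group]], y = .data$cnv_score, fill = .data[[group]])) +
    geom_violin(scale = "width") +
    labs(y = "CNV score", x = NULL, title = "Per-cell CNV burden") +
    theme_minimal() +
    theme(legend.position = "none")
}

#' Stacked per-sample composition bars
#'
#' @param prop_tbl Output of [proportions_by_sample()].
#' @return A ggplot object.
#' @export
plot_composition <- function(prop_tbl) {
  prop_tbl %>%
    mutate(stage = factor(.data$stage, levels = stage_levels())) %>%
    ggplot(aes(x = .data$sample_id, y = .data$proportion, fill = .data$cell_type)) +
    geom_col() +
    facet_wrap(~stage, scales = "free_x", nrow = 1) +
    labs(x = NULL, y = "proportion of cells", fill = "cell type") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 7))
}

#' Box plot of module scores by group
#'
#' @param score_tbl Module score tibble from [module_score()].
#' @param groups Data frame with `cell_id` and a grouping column.
#' @param group_col Grouping column name.
#' @return A ggplot object faceted by program.
#' @export
plot_module_scores <- function(score_tbl, groups, group_col = "group") {
  left_join(score_tbl, groups, by = "cell_id") %>%
    ggplot(aes(x = .data[[group_col]], y = .data$score, fill = .data[[group_col]])) +
    geom_boxplot(outlier.size = 0.4) +
    facet_wrap(~program, scales = "free_y") +
    labs(x = NULL, y = "module score") +
    theme_minimal() +
    theme(legend.position = "none")
}
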