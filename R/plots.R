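#' Plot a ROC curve
#'
#' @param object A `roc_curve` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-cycle AUC and metric distributions of a cross-validation run
#'
#' @param object An `ann_eval` from [train_eval_ann()].
#' @param ... Unused.
#' @return A ggplot object (boxplots of per-cycle metrics).
#' @export
autoplot.ann_eval <- function(object, ...) {
  long <- tidy.ann_eval(object)
  long$value[long$metric != "auc"] <- long$value[long$metric != "auc"] / 100
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5) +
    ggplot2::labs(
      x = NULL, y = "Value (metrics rescaled to [0, 1])",
      title = sprintf("Per-cycle metrics: %s features (%d cycles)",
                      object$feature_set, object$cycles)
    ) +
    ggplot2::theme_minimal()
}

#' Patterns-features heatmap of a cohort feature matrix
#'
#' Visualizes the lesion-by-feature panel after column-wise min-max
#' normalization, lesions ordered by class (adenocarcinoma first), with the
#' 0/1 class target appended as the last column.
#'
#' @param m A feature matrix from [build_feature_matrix()].
#' @return A ggplot object.
#' @export
plot_feature_matrix <- function(m) {
  norm <- normalize_feature_columns(m)
  norm <- dplyr::arrange(norm, .data$target)
  cols <- c(grep("^f[0-9]+$", names(norm), value = TRUE), "target")
  long <- tidyr::pivot_longer(
    dplyr::mutate(norm[, c("lesion_id", cols)],
                  row = dplyr::row_number()),
    dplyr::all_of(cols), names_to = "feature", values_to = "value"
  )
  long$feature <- factor(long$feature, levels = cols)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature, y = .data$row,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Feature (f1-f94, then class target)", y = "Lesion",
                  fill = "Normalized\nvalue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
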