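#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a sigmoid attenuation fit
#'
#' @param x A `sigmoid_fit` from [fit_sigmoid()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("f2", "f3", "f4"),
    estimate = c(x$f2, x$f3, x$f4)
  )
}

#' @rdname tidy.sigmoid_fit
#' @return For `glance()`: a one-row tibble with `rss` and `converged`.
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged)
}

#' Tidy a repeated cross-validation result
#'
#' @param x An `ann_eval` from [train_eval_ann()].
#' @param ... Unused.
#' @return `tidy()`: per-cycle metrics in long form (`cycle`, `metric`,
#'   `value`); `glance()`: one row per metric with `mean` and `sd` plus the
#'   run configuration.
#' @export
tidy.ann_eval <- function(x, ...) {
  tidyr::pivot_longer(
    x$cycle_metrics[, c("cycle", "auc", "sensitivity", "specificity",
                        "accuracy", "ppv", "npv")],
    -"cycle", names_to = "metric", values_to = "value"
  )
}

#' @rdname tidy.ann_eval
#' @export
glance.ann_eval <- function(x, ...) {
  dplyr::mutate(x$summary,
                feature_set = x$feature_set, folds = x$folds,
                cycles = x$cycles, hidden_units = x$hidden_units)
}
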