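#' Plot a power / Type-I table
#'
#' Bar chart of the proportion of tests with p below alpha per category,
#' faceted by model, coloured by method, with the nominal alpha as a dashed
#' reference line (the expected height of the null categories).
#'
#' @param object A `gxm_power_table` from [summarize_replicates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gxm_power_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$category, y = .data$proportion_raw,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$alpha[1], linetype = "dashed") +
    ggplot2::facet_wrap(~model) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("Proportion of tests with p < %g",
                                        object$alpha[1]),
                  fill = "Method") +
    ggplot2::theme_minimal()
}

#' Plot variable importance
#'
#' @param object A `gxm_tree` or `gxm_forest`.
#' @param top_n Show the `top_n` highest-ranked predictors (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gxm_forest <- function(object, top_n = 15, ...) {
  imp <- dplyr::slice_min(object$importance, .data$rank, n = top_n)
  ggplot2::ggplot(imp,
                  ggplot2::aes(x = stats::reorder(.data$predictor,
                                                  -.data$rank),
                               y = .data$score)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Impurity importance (max = 1)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gxm_forest
#' @export
autoplot.gxm_tree <- function(object, top_n = 15, ...) {
  imp <- dplyr::slice_min(
    dplyr::filter(object$importance,
                  .data$partition == object$importance$partition[1]),
    .data$rank, n = top_n)
  ggplot2::ggplot(object$importance,
                  ggplot2::aes(x = stats::reorder(.data$predictor,
                                                  -.data$rank),
                               y = .data$score, fill = .data$partition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Impurity importance (max = 1)",
                  fill = "Partition") +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of null interaction p-values
#'
#' Uniform QQ plot of p-values from effect-free SNP-CpG pairs; calibrated
#' tests track the identity line.
#'
#' @param pvalues Numeric vector of null p-values.
#' @return A ggplot object.
#' @export
plot_null_qq <- function(pvalues) {
  p <- sort(pvalues[!is.na(pvalues)])
  d <- tibble::tibble(expected = stats::ppoints(length(p)), observed = p)
  ggplot2::ggplot(d, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "Expected uniform quantile", y = "Observed p-value") +
    ggplot2::theme_minimal()
}
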