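#' Tidy an interaction-model fit
#'
#' @param x A `gxm_fit`.
#' @param ... Unused.
#' @return One row per design coefficient: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`.
#' @export
tidy.gxm_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.gxm_fit
#' @return For `glance()`: a one-row tibble with the method, model,
#'   interaction p-value, variance components (mixed fits), convergence and
#'   applicability flags, and sample size.
#' @export
glance.gxm_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, model = x$model_id,
    p_interaction = x$p_interaction,
    var_family = if (!is.null(x$varcomp)) unname(x$varcomp[1]) else NA_real_,
    var_residual = if (!is.null(x$varcomp)) unname(x$varcomp[2]) else NA_real_,
    converged = x$converged, applicable = x$applicable, n = x$n
  )
}

#' Tidy a polygenic heritability fit
#'
#' @param x A `gxm_h2`.
#' @param ... Unused.
#' @return A one-row tibble: `h2`, `sigma2_g`, `sigma2_e`, `loglik`,
#'   `boundary`, `converged`, `n`.
#' @export
tidy.gxm_h2 <- function(x, ...) {
  tibble::tibble(h2 = x$h2, sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e,
                 loglik = x$loglik, boundary = x$boundary,
                 converged = x$converged, n = x$n)
}

#' @rdname tidy.gxm_h2
#' @export
glance.gxm_h2 <- function(x, ...) tidy.gxm_h2(x)

#' Tidy tree and forest importance tables
#'
#' @param x A `gxm_tree` or `gxm_forest`.
#' @param ... Unused.
#' @return The importance tibble: `predictor`, `score` (max-normalized),
#'   `raw`, `rank`, `partition`, `model`.
#' @export
tidy.gxm_tree <- function(x, ...) x$importance

#' @rdname tidy.gxm_tree
#' @export
tidy.gxm_forest <- function(x, ...) x$importance
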