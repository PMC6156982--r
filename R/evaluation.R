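#' Proportion of tests below a significance threshold
#'
#' The empirical power (at causative sites) or Type-I error (at null sites):
#' the fraction of p-values strictly below `alpha`. Not-applicable tests
#' (`NA` p-values from untestable fits) must be excluded by the caller; an
#' empty p-value vector is an error rather than a silent 0/0.
#'
#' @param pvalues Numeric vector of p-values in [0, 1] (no `NA`).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return The proportion in [0, 1].
#' @export
#' @examples
#' estimate_power(c(0.01, 0.2, 0.04, 0.9), alpha = 0.05)
estimate_power <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) {
    stop("Cannot estimate a proportion from zero tests.", call. = FALSE)
  }
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1] with no missing values; drop ",
         "not-applicable tests first.", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1).",
                                     call. = FALSE)
  mean(pvalues < alpha)
}

#' Summarize replicate-level interaction tests into a power table
#'
#' Aggregates a long results table (one row per pair x model x method x
#' replicate, as produced by [run_pair_tests()] across replicates) into one
#' row per (category, model, method): the number of applicable tests, the
#' number excluded as not-applicable, and the proportion of p-values
#' strictly below `alpha`. Typical categories are one per causative pair, a
#' pooled background-SNP category, and pooled null categories with and
#' without the minor-allele-count filter.
#'
#' @param results Tibble with columns `category`, `model`, `method`,
#'   `p_value`, `applicable`.
#' @param alpha Significance level (default 0.05).
#' @param digits Decimals for the rounded `proportion` column shown alongside
#'   the full-precision `proportion_raw` (default 2).
#' @return A `gxm_power_table` tibble: `category`, `model`, `method`,
#'   `n_tests`, `n_not_applicable`, `proportion`, `proportion_raw`, `alpha`.
#' @export
summarize_replicates <- function(results, alpha = 0.05, digits = 2) {
  req <- c("category", "model", "method", "p_value", "applicable")
  missing <- setdiff(req, names(results))
  if (length(missing)) {
    stop("Results table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  empty <- dplyr::summarise(
    dplyr::group_by(results, .data$category, .data$model, .data$method),
    n_ok = sum(.data$applicable & !is.na(.data$p_value)), .groups = "drop")
  dropped <- dplyr::filter(empty, .data$n_ok == 0L)
  if (nrow(dropped)) {
    warning("Dropping ", nrow(dropped),
            " category/model/method cell(s) with zero applicable tests.",
            call. = FALSE)
  }
  out <- results |>
    dplyr::group_by(.data$category, .data$model, .data$method) |>
    dplyr::summarise(
      n_tests = sum(.data$applicable & !is.na(.data$p_value)),
      n_not_applicable = sum(!.data$applicable | is.na(.data$p_value)),
      proportion_raw = {
        ok <- .data$applicable & !is.na(.data$p_value)
        if (any(ok)) estimate_power(.data$p_value[ok], alpha) else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_tests > 0L) |>
    dplyr::mutate(proportion = round(.data$proportion_raw, digits),
                  alpha = alpha) |>
    dplyr::select("category", "model", "method", "n_tests",
                  "n_not_applicable", "proportion", "proportion_raw", "alpha")
  class(out) <- c("gxm_power_table", class(out))
  out
}
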