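#' Fixed-effect interaction test with a family term (Method I)
#'
#' Ordinary least squares fit of an interaction design with the family
#' identifier entered as a categorical term, absorbing between-family means.
#' The interaction p-value is the two-sided t-test on the `snp_meth`
#' coefficient with residual degrees of freedom.
#'
#' A monomorphic SNP or constant methylation regressor makes the interaction
#' untestable; such fits are returned with `applicable = FALSE` and an `NA`
#' p-value rather than an error (or p = 1), so downstream summaries can count
#' them separately. Any other rank deficiency is a hard error naming the
#' collinear columns.
#'
#' @param design A `gxm_design` from [build_design()].
#' @return A `gxm_fit` object; see [tidy.gxm_fit()] and [glance.gxm_fit()].
#' @export
fit_glm <- function(design) {
  stopifnot(inherits(design, "gxm_design"))
  na <- check_degenerate(design)
  if (!is.null(na)) return(na)

  d <- as.data.frame(design$x[, colnames(design$x) != "intercept",
                              drop = FALSE])
  d$.y <- design$response
  d$.fam <- factor(design$family_id)
  obj <- stats::lm(.y ~ ., data = d)
  cf <- stats::coef(obj)
  aliased <- names(cf)[is.na(cf)]
  core_aliased <- intersect(aliased, colnames(design$x))
  if (length(core_aliased)) {
    stop("Singular design: collinear column(s) ",
         paste(core_aliased, collapse = ", "), call. = FALSE)
  }
  sm <- summary(obj)$coefficients
  core <- intersect(colnames(design$x), rownames(sm))
  coefs <- tibble::tibble(
    term = core,
    estimate = unname(sm[core, 1]), std_error = unname(sm[core, 2]),
    statistic = unname(sm[core, 3]), p_value = unname(sm[core, 4])
  )
  new_gxm_fit(
    method = "GLM", model_id = design$model_id, coefficients = coefs,
    p_interaction = unname(sm["snp_meth", 4]),
    df_residual = obj$df.residual,
    varcomp = NULL, converged = TRUE, applicable = TRUE,
    n = nrow(design$x), object = obj, family_id = design$family_id
  )
}

#' Family random-intercept mixed-model interaction test (Method II)
#'
#' Linear mixed model with a random intercept per family, estimated by
#' restricted maximum likelihood via \pkg{lme4}; the interaction p-value is a
#' Wald test on the `snp_meth` coefficient (normal reference by default,
#' residual-df t as an option - with a couple hundred families the two are
#' practically identical). Supplying a kinship matrix replaces the family
#' intercept with the full polygenic covariance `2 * Phi * sigma2_g`,
#' estimated by the same eigen-rotated REML profile the heritability module
#' uses.
#'
#' @param design A `gxm_design`.
#' @param df_method `"wald_z"` (default) or `"wald_t"`.
#' @param kinship Optional kinship matrix (rows aligned with the design) for
#'   the polygenic-covariance variant.
#' @return A `gxm_fit`. Non-convergence is flagged (`converged = FALSE`) and
#'   the p-value withheld (`NA`).
#' @export
fit_mixed <- function(design, df_method = c("wald_z", "wald_t"),
                      kinship = NULL) {
  stopifnot(inherits(design, "gxm_design"))
  df_method <- match.arg(df_method)
  na <- check_degenerate(design, method = "MIXED")
  if (!is.null(na)) return(na)
  if (length(unique(design$family_id)) < 2L && is.null(kinship)) {
    stop("At least two families are required for the mixed model.",
         call. = FALSE)
  }
  if (!is.null(kinship)) {
    return(fit_mixed_kinship(design, kinship, df_method))
  }

  d <- as.data.frame(design$x)
  d$.y <- design$response
  d$.fam <- factor(design$family_id)
  fixed <- paste(colnames(design$x), collapse = " + ")
  form <- stats::as.formula(paste(".y ~ 0 +", fixed, "+ (1 | .fam)"))
  # uncentred age^2 triggers lme4's predictor-scale warning; harmless here
  obj <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))
  ))
  converged <- length(obj@optinfo$conv$lme4$messages) == 0L &&
    obj@optinfo$conv$opt == 0L
  sm <- summary(obj)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  z <- est / se
  df_res <- nrow(design$x) - ncol(design$x)
  p <- if (df_method == "wald_z") 2 * stats::pnorm(-abs(z)) else
    2 * stats::pt(-abs(z), df_res)
  vc <- as.data.frame(lme4::VarCorr(obj))
  varcomp <- c(family = vc$vcov[vc$grp == ".fam"],
               residual = vc$vcov[vc$grp == "Residual"])
  coefs <- tibble::tibble(term = rownames(sm), estimate = unname(est),
                          std_error = unname(se), statistic = unname(z),
                          p_value = unname(p))
  new_gxm_fit(
    method = "MIXED", model_id = design$model_id, coefficients = coefs,
    p_interaction = if (converged) unname(p["snp_meth"]) else NA_real_,
    df_residual = df_res, varcomp = varcomp,
    converged = converged, applicable = TRUE,
    n = nrow(design$x), object = obj, family_id = design$family_id
  )
}

fit_mixed_kinship <- function(design, kinship, df_method) {
  fit <- reml_kinship(design$response, design$x, kinship)
  est <- fit$beta; se <- fit$se_beta
  z <- est / se
  df_res <- nrow(design$x) - ncol(design$x)
  p <- if (df_method == "wald_z") 2 * stats::pnorm(-abs(z)) else
    2 * stats::pt(-abs(z), df_res)
  coefs <- tibble::tibble(term = colnames(design$x), estimate = unname(est),
                          std_error = unname(se), statistic = unname(z),
                          p_value = unname(p))
  new_gxm_fit(
    method = "MIXED_KINSHIP", model_id = design$model_id,
    coefficients = coefs,
    p_interaction = unname(p[coefs$term == "snp_meth"]),
    df_residual = df_res,
    varcomp = c(genetic = fit$sigma2_g, residual = fit$sigma2_e),
    converged = fit$converged, applicable = TRUE,
    n = nrow(design$x), object = NULL, family_id = design$family_id
  )
}

#' Cluster-robust (sandwich) standard errors for a fixed-effect fit
#'
#' Replaces the model-based standard errors of a [fit_glm()] result with
#' family-clustered sandwich estimates and recomputes the interaction
#' p-value. Provided as an explicitly non-default diagnostic: with rare
#' variants (low minor allele count) the cluster-robust variance is poorly
#' estimated and the interaction test becomes anticonservative.
#'
#' @param fit A converged `gxm_fit` from [fit_glm()].
#' @param type Sandwich flavour passed to [sandwich::vcovCL()] (default
#'   `"HC1"`).
#' @return A `gxm_fit` with `method = "GLM_SANDWICH"`.
#' @export
sandwich_se <- function(fit, type = "HC1") {
  stopifnot(inherits(fit, "gxm_fit"))
  if (!identical(fit$method, "GLM") || is.null(fit$object)) {
    stop("Sandwich standard errors are defined for fit_glm() results.",
         call. = FALSE)
  }
  if (!fit$converged || !fit$applicable) {
    stop("Sandwich standard errors require a converged, applicable fit.",
         call. = FALSE)
  }
  if (length(unique(fit$family_id)) < 2L) {
    stop("Cluster-robust errors need at least two families.", call. = FALSE)
  }
  vc <- sandwich::vcovCL(fit$object, cluster = fit$family_id, type = type)
  keep <- intersect(fit$coefficients$term, rownames(vc))
  se <- sqrt(diag(vc))[keep]
  est <- fit$coefficients$estimate[match(keep, fit$coefficients$term)]
  z <- est / se
  p <- 2 * stats::pt(-abs(z), fit$df_residual)
  coefs <- tibble::tibble(term = keep, estimate = est, std_error = se,
                          statistic = z, p_value = p)
  out <- fit
  out$method <- "GLM_SANDWICH"
  out$coefficients <- coefs
  out$p_interaction <- unname(p[keep == "snp_meth"])
  out
}

check_degenerate <- function(design, method = "GLM") {
  degen <- character(0)
  for (col in intersect(c("snp", "meth", "snp_meth"), colnames(design$x))) {
    if (stats::var(design$x[, col]) < .Machine$double.eps * 100) {
      degen <- c(degen, col)
    }
  }
  if (!length(degen)) return(NULL)
  check_degenerate_result(design, method)
}

check_degenerate_result <- function(design, method) {
  new_gxm_fit(
    method = method, model_id = design$model_id,
    coefficients = tibble::tibble(term = character(), estimate = numeric(),
                                  std_error = numeric(), statistic = numeric(),
                                  p_value = numeric()),
    p_interaction = NA_real_, df_residual = NA_integer_, varcomp = NULL,
    converged = NA, applicable = FALSE, n = nrow(design$x),
    object = NULL, family_id = design$family_id
  )
}

new_gxm_fit <- function(method, model_id, coefficients, p_interaction,
                        df_residual, varcomp, converged, applicable, n,
                        object, family_id) {
  structure(list(
    method = method, model_id = model_id, coefficients = coefficients,
    p_interaction = p_interaction, df_residual = df_residual,
    varcomp = varcomp, converged = converged, applicable = applicable,
    n = n, object = object, family_id = family_id
  ), class = "gxm_fit")
}

#' @export
print.gxm_fit <- function(x, ...) {
  cat("<gxm_fit> method ", x$method, ", model ", x$model_id, ", n = ", x$n,
      "\n", sep = "")
  if (!x$applicable) {
    cat("  not applicable (degenerate SNP or methylation regressor)\n")
  } else {
    cat("  interaction p = ", format.pval(x$p_interaction, digits = 3),
        if (!isTRUE(x$converged)) "  [NOT CONVERGED]", "\n", sep = "")
  }
  invisible(x)
}

#' Run a batch of SNP-CpG interaction tests
#'
#' Fits the requested model x method grid for every SNP-CpG pair and returns
#' one row per (pair, model, method) with the interaction estimate and
#' p-value - the long results table the power/Type-I summaries consume.
#'
#' @param pairs Tibble with columns `snp_id` and `cpg_id` (extra columns such
#'   as `category` are carried through).
#' @param genotypes `gxm_genotypes`.
#' @param methylation `gxm_methylation`.
#' @param traits `gxm_traits` from [derive_traits()] (with the delta-CpG
#'   attribute when models 2a/2b are requested).
#' @param models Subset of `c("1a", "1b", "2a", "2b")`.
#' @param methods Subset of `c("glm", "mixed")`.
#' @param cpg_visit Which visit's beta-values models 1a/1b use (default 4).
#' @param replicate Optional replicate label carried into the output.
#' @return Tibble: pair columns, `model`, `method`, `estimate`, `std_error`,
#'   `p_value`, `converged`, `applicable`.
#' @export
run_pair_tests <- function(pairs, genotypes, methylation, traits,
                           models = "1a", methods = c("glm", "mixed"),
                           cpg_visit = 4L, replicate = NA_integer_) {
  stopifnot(all(models %in% c("1a", "1b", "2a", "2b")),
            all(methods %in% c("glm", "mixed")))
  beta_mat <- if (cpg_visit == 4L) methylation$beta_visit4 else
    methylation$beta_visit2
  delta_mat <- attr(traits, "delta_cpg")
  grid <- tidyr::expand_grid(pair = seq_len(nrow(pairs)),
                             model = models, method = methods)
  purrr::pmap_dfr(grid, function(pair, model, method) {
    row <- pairs[pair, ]
    snp <- genotypes$dosages[, row$snp_id]
    cpg <- if (model %in% c("1a", "1b")) beta_mat[, row$cpg_id] else
      delta_mat[, row$cpg_id]
    des <- build_design(model, snp, cpg, traits)
    # a singular design (e.g. a single-carrier SNP whose interaction column
    # is proportional to its dosage) is untestable in a batch run
    fit <- tryCatch(
      if (method == "glm") fit_glm(des) else fit_mixed(des),
      error = function(e) check_degenerate_result(des, toupper(method))
    )
    est <- se <- NA_real_
    if (fit$applicable && nrow(fit$coefficients)) {
      i <- match("snp_meth", fit$coefficients$term)
      est <- fit$coefficients$estimate[i]
      se <- fit$coefficients$std_error[i]
    }
    dplyr::bind_cols(
      row,
      tibble::tibble(model = model, method = toupper(method),
                     replicate = replicate,
                     estimate = est, std_error = se,
                     p_value = fit$p_interaction,
                     converged = isTRUE(fit$converged),
                     applicable = fit$applicable)
    )
  })
}
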