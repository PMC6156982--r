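#' Generating-model effect configuration
#'
#' Calibrates every coefficient of the generating model
#' \deqn{Post = \beta_0 + \sum_k [\beta_{1k} SNP_k + \beta_{2k}(1-CpG_k) +
#'   \beta_{3k} SNP_k (1-CpG_k)] + \sum_j \beta_{bg,j} SNP_j +
#'   \beta_C C + \gamma Pre + g + \epsilon}
#' from interpretable targets rather than raw coefficients. The calibration
#' is analytic and deterministic:
#'
#' * Each causal SNP's marginal standardized variance contribution (its
#'   expected b-squared) is fixed by `b2_targets`; the marginal effect is
#'   split between the SNP main effect and the interaction with the paired
#'   CpG by `interaction_share` (the interaction pathway acts through
#'   `1 - CpG`, so its mean contributes to the marginal SNP effect).
#' * `sigma2_poly` is solved so that (polygenic + total SNP additive)
#'   variance equals `target_h2` of the covariate-adjusted phenotypic
#'   variance `v_adj`.
#' * The squared-correlation b2 estimator is upward-biased in finite,
#'   family-clustered samples: under the null E[r^2] ~ tr(Rx Ry) / n^2, with
#'   Rx = 2*Phi the dosage correlation among relatives and Ry the residual
#'   correlation. When a kinship matrix is supplied this bias is computed
#'   exactly and `b2_targets` are treated as targets for the *estimator's*
#'   expectation; true contributions are deflated accordingly (floored at
#'   10% of the target so every causal locus keeps a real effect).
#' * Pre-treatment level enters with coefficient `gamma = corr_pre`, sized so
#'   that corr(Pre, adjusted Post) is `corr_pre`.
#'
#' @param snp_map,cpg_map Marker metadata ([snp_metadata()], [cpg_metadata()]).
#' @param genotypes Optional `gxm_genotypes` holding the study's realized
#'   dosages. Genotypes are drawn once and reused across replicates, so each
#'   locus's standardized contribution is defined against its *realized*
#'   dosage variance; without this argument the Hardy-Weinberg expectation
#'   `2 maf (1 - maf)` is used instead.
#' @param covariates Optional fixed covariate matrix (age, age squared, sex)
#'   of the study pedigree. With both `genotypes` and `covariates` supplied,
#'   marginal SNP effects are solved from the realized covariate-projected
#'   dosage cross-products, so that each causal locus's implied marginal
#'   moment hits its b2 target despite chance cross-locus correlations in
#'   the fixed genotype draw.
#' @param kinship Optional kinship matrix of the study pedigree, used for the
#'   exact finite-sample b2 bias; without it the bias falls back to 1/n.
#' @param n_individuals Sample size the bias correction assumes (default 680).
#' @param target_h2 Narrow-sense heritability of adjusted Post (default 0.43).
#' @param b2_targets Expected per-locus b2 of the 5 causal SNPs
#'   (default `c(0.0210, 0.0008, 0.0070, 0.0004, 0.0090)`).
#' @param interaction_share Fraction of each causal SNP's marginal effect
#'   routed through the SNP x (1 - CpG) interaction (default 0.8).
#' @param bg_var_frac Variance fraction (of the adjusted, Pre-free scale)
#'   contributed by each background SNP (default 0.001).
#' @param cpg_var_frac Variance fraction contributed by each causal CpG main
#'   effect (default 0.002).
#' @param corr_pre Target correlation between Pre and adjusted Post
#'   (default 0.7).
#' @param v_adj Absolute covariate-adjusted variance of Post on the log-TG
#'   scale (default 0.25, i.e. sd 0.5).
#' @param visit_noise_frac Fraction of the non-genetic residual assigned to
#'   per-visit measurement noise (default 0.5; two visits are averaged, so
#'   half of this reaches Post).
#' @param mu_pre,mu_post Means of Pre and Post on the log-TG scale.
#' @param beta_age,beta_age2,beta_sex Covariate effects.
#' @param cpg_visit Which visit's beta-value enters the generating model
#'   (4, the post-treatment visit, by default; 2 is available).
#' @param treatment_effect Visit-4 mean shift at causal CpGs; must match the
#'   value passed to [simulate_methylation()].
#' @return An object of class `gxm_effects`: a list of all generating
#'   coefficients and variance components, including `sigma2_poly`,
#'   `sigma2_e`, `sigma2_visit` and the per-locus `beta1`, `beta2`, `beta3`.
#' @export
effect_config <- function(snp_map, cpg_map,
                          genotypes = NULL,
                          covariates = NULL,
                          kinship = NULL,
                          n_individuals = 680L,
                          target_h2 = 0.43,
                          b2_targets = c(0.0210, 0.0008, 0.0070, 0.0004, 0.0090),
                          interaction_share = 0.8,
                          bg_var_frac = 0.001,
                          cpg_var_frac = 0.002,
                          corr_pre = 0.7,
                          v_adj = 0.25,
                          visit_noise_frac = 0.5,
                          mu_pre = 5.0,
                          mu_post = 4.8,
                          beta_age = 0.005,
                          beta_age2 = 1e-5,
                          beta_sex = 0.05,
                          cpg_visit = 4L,
                          treatment_effect = -0.05) {
  stopifnot(target_h2 >= 0, target_h2 < 1, v_adj > 0,
            corr_pre >= 0, corr_pre < 1, cpg_visit %in% c(2L, 4L))
  causal <- dplyr::filter(snp_map, .data$role == "main_causal")
  bg <- dplyr::filter(snp_map, .data$role == "background")
  ccpg <- dplyr::filter(cpg_map, !is.na(.data$paired_snp))
  ccpg <- ccpg[match(causal$snp_id, ccpg$paired_snp), ]
  if (anyNA(ccpg$cpg_id)) {
    stop("Every main_causal SNP needs exactly one paired CpG.", call. = FALSE)
  }
  n <- as.integer(n_individuals)

  # moments of the CpG regressor (1 - beta-value) at the visit used
  mean_cpg <- if (cpg_visit == 4L) {
    pmin(pmax(ccpg$mean_beta + treatment_effect, 0.01), 0.99)
  } else {
    ccpg$mean_beta
  }
  var_cpg <- mean_cpg * (1 - mean_cpg) / (ccpg$concentration + 1)
  m_bar <- 1 - mean_cpg

  p_c <- causal$maf
  if (!is.null(genotypes)) {
    dos_c <- genotypes$dosages[, causal$snp_id, drop = FALSE]
    var_snp <- apply(dos_c, 2, stats::var)
    e_snp2 <- var_snp + colMeans(dos_c)^2
    var_bg <- apply(genotypes$dosages[, bg$snp_id, drop = FALSE], 2,
                    stats::var)
  } else {
    var_snp <- 2 * p_c * (1 - p_c)
    e_snp2 <- var_snp + (2 * p_c)^2
    var_bg <- 2 * bg$maf * (1 - bg$maf)
  }
  if (any(var_snp <= 0)) {
    stop("A causal SNP is monomorphic in the realized genotypes.",
         call. = FALSE)
  }
  var_bg <- pmax(var_bg, 1e-8)

  f_pre <- corr_pre^2
  v_b2den <- (1 - f_pre) * v_adj          # adjusted variance with Pre removed
  v_bg_total <- nrow(bg) * bg_var_frac * v_b2den
  beta_bg <- sqrt(bg_var_frac * v_b2den / var_bg)

  # fixed point: sigma2_poly depends on realized additive variance, which
  # depends on the bias-corrected b2, which depends on sigma2_poly
  b2_true <- b2_targets
  sigma2_poly <- 0
  bias <- 1 / n
  for (iter in 1:4) {
    v_causal_add <- sum(b2_true) * v_b2den
    sigma2_poly <- target_h2 * v_adj - v_causal_add - v_bg_total
    if (sigma2_poly < 0) {
      stop("target_h2 too small for the configured SNP contributions.",
           call. = FALSE)
    }
    h2_resid <- sigma2_poly / v_b2den
    bias <- if (is.null(kinship)) {
      1 / n
    } else {
      K <- 2 * kinship
      off2 <- sum(K^2) - sum(diag(K)^2)
      (n + h2_resid * off2) / n^2
    }
    # E[r^2] ~ rho^2 + bias * (1 - rho^2)^2; solve for the true rho^2
    bt <- b2_targets
    for (k in 1:3) bt <- b2_targets - bias * (1 - bt)^2
    b2_true <- pmax(bt, 0.1 * b2_targets)
  }

  # marginal standardized effect per causal locus
  alpha_naive <- sqrt(b2_true * v_b2den / var_snp)
  alpha <- alpha_naive
  if (!is.null(genotypes)) {
    # With a fixed genotype draw, chance cross-locus correlations shift each
    # SNP's realized marginal slope. Solve the 5 marginal-moment equations
    #   sum_j alpha_j <Mx_j, Mx_k>/n + sum_bg beta_j <Mx_j, Mx_k>/n = t_k
    # (M projects out the fixed covariates) so the implied marginal effect
    # matches its target on this design.
    n_obs <- nrow(genotypes$dosages)
    Xfix <- if (is.null(covariates)) matrix(1, n_obs, 1) else
      cbind(1, as.matrix(covariates))
    qrX <- qr(Xfix)
    proj <- function(A) A - qr.fitted(qrX, A)
    Mc <- proj(dos_c)
    Mb <- proj(genotypes$dosages[, bg$snp_id, drop = FALSE])
    C <- crossprod(Mc) / n_obs
    Cb <- crossprod(Mc, Mb) / n_obs
    t_k <- sqrt(b2_true * v_b2den) * sqrt(var_snp)
    alpha_solved <- tryCatch(
      as.numeric(solve(C, t_k - Cb %*% beta_bg)),
      error = function(e) alpha_naive)
    # guard against pathological designs; keep effects positive and sane
    ok <- alpha_solved > 0.25 * alpha_naive & alpha_solved < 4 * alpha_naive
    alpha <- ifelse(ok, alpha_solved, alpha_naive)
  }
  beta3 <- interaction_share * alpha / m_bar
  beta1 <- (1 - interaction_share) * alpha
  beta2 <- sqrt(cpg_var_frac * v_b2den / var_cpg)
  v_int <- beta3^2 * e_snp2 * var_cpg
  v_cpg_main <- rep(cpg_var_frac * v_b2den, length(beta2))

  sigma2_e_tot <- v_b2den - sum(b2_true) * v_b2den - v_bg_total -
    sum(v_int) - sum(v_cpg_main) - sigma2_poly
  if (sigma2_e_tot <= 0) {
    stop("Variance budget exhausted: reduce target_h2, cpg_var_frac or ",
         "interaction_share.", call. = FALSE)
  }
  sigma2_visit <- visit_noise_frac * sigma2_e_tot
  sigma2_e <- sigma2_e_tot - sigma2_visit / 2

  structure(list(
    snp_id = causal$snp_id, cpg_id = ccpg$cpg_id,
    beta1 = beta1, beta2 = beta2, beta3 = beta3,
    alpha = alpha, b2_true = b2_true, b2_targets = b2_targets,
    b2_bias = bias,
    bg_snp_id = bg$snp_id, beta_background = beta_bg,
    gamma_pre = corr_pre,
    beta_age = beta_age, beta_age2 = beta_age2, beta_sex = beta_sex,
    mu_pre = mu_pre, mu_post = mu_post,
    sigma2_poly = sigma2_poly, sigma2_e = sigma2_e,
    sigma2_visit = sigma2_visit,
    var_pre = v_adj, v_adj = v_adj, v_b2den = v_b2den,
    target_h2 = target_h2, cpg_visit = cpg_visit,
    mean_cpg_regressor = m_bar, var_cpg = var_cpg
  ), class = "gxm_effects")
}

#' @export
print.gxm_effects <- function(x, ...) {
  cat("<gxm_effects> generating-model configuration\n")
  cat("  target h2:", x$target_h2,
      " sigma2_poly:", signif(x$sigma2_poly, 4),
      " sigma2_e:", signif(x$sigma2_e, 4), "\n")
  cat("  causal beta3:", paste(signif(x$beta3, 3), collapse = ", "), "\n")
  invisible(x)
}
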