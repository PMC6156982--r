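#' Simulate pre/post-treatment triglycerides under the generating model
#'
#' Draws four visit-level triglyceride measurements per individual. The
#' post-treatment latent trait follows the generating model: causal SNP main
#' effects, CpG effects coded as (1 - beta-value), SNP x (1 - CpG)
#' interactions, 100 tiny background SNP effects, covariates (age, age
#' squared, sex), a pre-treatment anchor `gamma * Pre`, a polygenic component
#' `g ~ MVN(0, 2 * Phi * sigma2_poly)` drawn family-by-family, and an i.i.d.
#' residual. Visit-level log-TG values add independent measurement noise, and
#' TG is exponentiated so all values are strictly positive.
#'
#' @param pedigree Pedigree tibble (supplies age and sex).
#' @param genotypes `gxm_genotypes` from [simulate_genotypes()].
#' @param methylation `gxm_methylation` from [simulate_methylation()].
#' @param effects `gxm_effects` from [effect_config()].
#' @param kinship Kinship matrix from [kinship_matrix()].
#' @param seed Integer seed.
#' @return A tibble: `individual_id`, `family_id`, `TG1`-`TG4` (positive),
#'   `age`, `sex`.
#' @export
simulate_phenotypes <- function(pedigree, genotypes, methylation, effects,
                                kinship, seed = 1L) {
  validate_pedigree(pedigree)
  ids <- pedigree$individual_id
  if (!identical(rownames(genotypes$dosages), ids) ||
      !identical(rownames(methylation$beta_visit2), ids) ||
      !identical(rownames(kinship), ids)) {
    stop("Genotypes, methylation and kinship must be indexed by the same ",
         "individuals, in pedigree order.", call. = FALSE)
  }
  n <- length(ids)
  ef <- effects

  cpg_mat <- if (ef$cpg_visit == 4L) methylation$beta_visit4 else
    methylation$beta_visit2
  snp_c <- genotypes$dosages[, ef$snp_id, drop = FALSE]
  cpg_c <- 1 - cpg_mat[, ef$cpg_id, drop = FALSE]
  snp_bg <- genotypes$dosages[, ef$bg_snp_id, drop = FALSE]

  genetic_fixed <-
    snp_c %*% ef$beta1 + cpg_c %*% ef$beta2 +
    (snp_c * cpg_c) %*% ef$beta3 + snp_bg %*% ef$beta_background

  sexm <- as.numeric(pedigree$sex == "male")
  covar <- ef$beta_age * pedigree$age + ef$beta_age2 * pedigree$age^2 +
    ef$beta_sex * sexm

  with_seed(sub_seed(seed, "phenotypes"), {
    s2v <- ef$sigma2_visit
    # Pre: latent + visit noise so that the observed average has variance
    # var_pre exactly and the gamma * Pre pathway is in terms of observed Pre
    lat_var <- max(ef$var_pre - s2v / 2, 0)
    pre_lat <- stats::rnorm(n, 0, sqrt(lat_var))
    e1 <- stats::rnorm(n, 0, sqrt(s2v))
    e2 <- stats::rnorm(n, 0, sqrt(s2v))
    pre_obs <- ef$mu_pre + pre_lat + (e1 + e2) / 2

    g <- polygenic_draw(pedigree, kinship, ef$sigma2_poly)
    eps <- stats::rnorm(n, 0, sqrt(ef$sigma2_e))

    centre <- ef$mu_post - ef$gamma_pre * ef$mu_pre -
      mean(genetic_fixed) - mean(covar)
    post_core <- centre + as.numeric(genetic_fixed) + covar +
      ef$gamma_pre * pre_obs + g + eps

    e3 <- stats::rnorm(n, 0, sqrt(s2v))
    e4 <- stats::rnorm(n, 0, sqrt(s2v))

    tibble::tibble(
      individual_id = ids,
      family_id = pedigree$family_id,
      TG1 = exp(ef$mu_pre + pre_lat + e1),
      TG2 = exp(ef$mu_pre + pre_lat + e2),
      TG3 = exp(post_core + e3),
      TG4 = exp(post_core + e4),
      age = pedigree$age,
      sex = pedigree$sex
    )
  })
}

# family-block multivariate normal draw with covariance 2 * Phi * sigma2
polygenic_draw <- function(pedigree, kinship, sigma2) {
  n <- nrow(pedigree)
  if (sigma2 <= 0) return(numeric(n))
  g <- numeric(n)
  for (fid in unique(pedigree$family_id)) {
    idx <- which(pedigree$family_id == fid)
    K <- 2 * kinship[idx, idx, drop = FALSE] * sigma2
    L <- chol(K + diag(1e-10, length(idx)))
    g[idx] <- as.numeric(crossprod(L, stats::rnorm(length(idx))))
  }
  g
}
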