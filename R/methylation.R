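#' Default CpG metadata for a simulated study
#'
#' Five causal CpGs sit just downstream of their paired causal SNPs; null
#' CpGs populate chromosomes 21 and 22 so that SNP-CpG pairs with no
#' simulated effect can be formed for the empirical null.
#'
#' @param snp_map SNP metadata tibble ([snp_metadata()]); causal CpGs are
#'   placed 5 kb downstream of each `main_causal` SNP.
#' @param n_null_per_chrom Null CpGs per null chromosome (default 120).
#' @param mean_beta Marginal methylation mean (visit 2) for every CpG.
#' @param concentration Beta-distribution concentration (mean * conc and
#'   (1 - mean) * conc are the two shape parameters).
#' @param seed Seed for metadata draws.
#' @return Tibble: `cpg_id`, `chromosome`, `position`, `mean_beta`,
#'   `concentration`, `paired_snp` (id or `NA`).
#' @export
cpg_metadata <- function(snp_map,
                         n_null_per_chrom = 120L,
                         mean_beta = 0.6,
                         concentration = 10,
                         seed = 1L) {
  causal_snps <- dplyr::filter(snp_map, .data$role == "main_causal")
  with_seed(sub_seed(seed, "cpg_metadata"), {
    causal <- tibble::tibble(
      cpg_id = sprintf("cpg_c%02d", seq_len(nrow(causal_snps))),
      chromosome = causal_snps$chromosome,
      position = causal_snps$position + 5000L,
      mean_beta = mean_beta,
      concentration = concentration,
      paired_snp = causal_snps$snp_id
    )
    null <- purrr::map_dfr(c(21L, 22L), function(chr) {
      tibble::tibble(
        cpg_id = sprintf("cpg_n%d_%03d", chr, seq_len(n_null_per_chrom)),
        chromosome = chr,
        position = sort(sample.int(5e7, n_null_per_chrom)),
        mean_beta = mean_beta,
        concentration = concentration,
        paired_snp = NA_character_
      )
    })
    dplyr::bind_rows(causal, null)
  })
}

#' Simulate methylation beta-values at two visits
#'
#' Beta-values are Beta-distributed marginally with the configured mean and
#' concentration; visit-4 values are coupled to visit-2 values through a
#' Gaussian copula with correlation `rho`, so both visits keep exact Beta
#' marginals while being longitudinally correlated. At CpGs flagged as
#' treatment-responsive (`paired_snp` not `NA`), the visit-4 marginal mean is
#' shifted by `treatment_effect` (a negative value models drug-induced
#' demethylation), truncated to (0.01, 0.99).
#'
#' @param pedigree Pedigree tibble.
#' @param cpg_metadata CpG tibble ([cpg_metadata()]); `mean_beta` must lie in
#'   (0, 1) and `concentration` must be positive.
#' @param treatment_effect Shift of the visit-4 mean at causal CpGs
#'   (default -0.05).
#' @param rho Visit-2/visit-4 copula correlation in [0, 1] (default 0.9).
#' @param seed Integer seed.
#' @return A `gxm_methylation` list: `beta_visit2`, `beta_visit4`
#'   (individuals x CpGs matrices in [0, 1]) and `map`.
#' @export
simulate_methylation <- function(pedigree, cpg_metadata,
                                 treatment_effect = -0.05,
                                 rho = 0.9,
                                 seed = 1L) {
  validate_pedigree(pedigree)
  if (any(cpg_metadata$mean_beta <= 0 | cpg_metadata$mean_beta >= 1)) {
    stop("CpG `mean_beta` must lie strictly inside (0, 1).", call. = FALSE)
  }
  if (any(cpg_metadata$concentration <= 0)) {
    stop("CpG `concentration` must be positive.", call. = FALSE)
  }
  if (rho < 0 || rho > 1) {
    stop("`rho` must lie in [0, 1].", call. = FALSE)
  }
  n <- nrow(pedigree)
  m <- nrow(cpg_metadata)
  mean2 <- cpg_metadata$mean_beta
  mean4 <- ifelse(is.na(cpg_metadata$paired_snp), mean2,
                  pmin(pmax(mean2 + treatment_effect, 0.01), 0.99))
  conc <- cpg_metadata$concentration
  a2 <- mean2 * conc; b2 <- (1 - mean2) * conc
  a4 <- mean4 * conc; b4 <- (1 - mean4) * conc

  with_seed(sub_seed(seed, "methylation"), {
    z2 <- matrix(stats::rnorm(n * m), n, m)
    eps <- matrix(stats::rnorm(n * m), n, m)
    z4 <- rho * z2 + sqrt(1 - rho^2) * eps
    u2 <- stats::pnorm(z2)
    u4 <- stats::pnorm(z4)
    beta2 <- matrix(stats::qbeta(u2, rep(a2, each = n), rep(b2, each = n)), n, m)
    beta4 <- matrix(stats::qbeta(u4, rep(a4, each = n), rep(b4, each = n)), n, m)
    dimnames(beta2) <- dimnames(beta4) <-
      list(pedigree$individual_id, cpg_metadata$cpg_id)
    structure(list(beta_visit2 = beta2, beta_visit4 = beta4,
                   map = cpg_metadata),
              class = "gxm_methylation")
  })
}

#' @export
print.gxm_methylation <- function(x, ...) {
  cat("<gxm_methylation> ", nrow(x$beta_visit2), " individuals x ",
      ncol(x$beta_visit2), " CpGs, visits 2 and 4\n", sep = "")
  invisible(x)
}
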