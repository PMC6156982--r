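#' Set up a simulated study (pedigree, kinship, genotypes, effects)
#'
#' Builds the replicate-invariant part of a simulated study: the pedigree and
#' its kinship matrix, the marker panel, one fixed set of genotypes, and the
#' calibrated generating-model effects. As in family studies where genotypes
#' are measured once, genotypes are shared across replicates; methylation and
#' phenotypes are redrawn per replicate with [simulate_replicate()].
#'
#' @param n_individuals Individuals per replicate (default 680).
#' @param seed Study seed; every stream derives from it via [sub_seed()].
#' @param snp_map,cpg_map Optional marker metadata; defaults to
#'   [snp_metadata()] / [cpg_metadata()] under the study seed.
#' @param effects Optional `gxm_effects`; defaults to [effect_config()]
#'   calibrated on this study's kinship matrix.
#' @param ... Passed on to [effect_config()] when `effects` is NULL.
#' @return A `gxm_study` list: `pedigree`, `kinship`, `genotypes`,
#'   `snp_map`, `cpg_map`, `effects`, `seed`.
#' @export
#' @examples
#' st <- simulate_study(n_individuals = 60, seed = 1)
#' rep1 <- simulate_replicate(st, 1)
#' names(rep1)
simulate_study <- function(n_individuals = 680L, seed = 1L,
                           snp_map = NULL, cpg_map = NULL,
                           effects = NULL, ...) {
  pedigree <- build_pedigrees(n_individuals, seed = sub_seed(seed, "pedigree"))
  kin <- kinship_matrix(pedigree)
  if (is.null(snp_map)) snp_map <- snp_metadata(seed = seed)
  if (is.null(cpg_map)) cpg_map <- cpg_metadata(snp_map, seed = seed)
  genotypes <- simulate_genotypes(pedigree, snp_map, seed = seed)
  if (is.null(effects)) {
    covs <- cbind(age = pedigree$age, age2 = pedigree$age^2,
                  sex = as.numeric(pedigree$sex == "male"))
    effects <- effect_config(snp_map, cpg_map, genotypes = genotypes,
                             covariates = covs, kinship = kin,
                             n_individuals = n_individuals, ...)
  }
  structure(list(pedigree = pedigree, kinship = kin, genotypes = genotypes,
                 snp_map = snp_map, cpg_map = cpg_map, effects = effects,
                 seed = seed),
            class = "gxm_study")
}

#' Draw one replicate of a simulated study
#'
#' @param study A `gxm_study` from [simulate_study()].
#' @param replicate Replicate index (1-based); determines the substream.
#' @return A list with `methylation` (`gxm_methylation`), `phenotypes`
#'   (tibble) and `traits` ([derive_traits()] output).
#' @export
simulate_replicate <- function(study, replicate = 1L) {
  meth <- simulate_methylation(
    study$pedigree, study$cpg_map,
    seed = sub_seed(study$seed, "methylation", replicate)
  )
  phen <- simulate_phenotypes(
    study$pedigree, study$genotypes, meth, study$effects, study$kinship,
    seed = sub_seed(study$seed, "phenotypes", replicate)
  )
  list(methylation = meth, phenotypes = phen,
       traits = derive_traits(phen, meth))
}

#' @export
print.gxm_study <- function(x, ...) {
  cat("<gxm_study> ", nrow(x$pedigree), " individuals in ",
      length(unique(x$pedigree$family_id)), " families; ",
      nrow(x$snp_map), " SNPs, ", nrow(x$cpg_map), " CpGs; seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}
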