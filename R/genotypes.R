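#' Default SNP metadata for a simulated study
#'
#' Lays out the marker panel the generator emulates: 5 causal SNPs (each with
#' a paired downstream CpG) and 100 tiny-effect "background" SNPs on
#' chromosomes 1-20, plus effect-free SNPs on chromosomes 21 and 22 that
#' supply the empirical null. Positions are 1-based base pairs.
#'
#' @param causal_maf Minor allele frequencies of the 5 causal SNPs.
#' @param n_background Number of background SNPs (default 100).
#' @param n_null_per_chrom Number of null SNPs placed on each of chromosomes
#'   21 and 22 (default 150).
#' @param null_maf_range MAF range for null SNPs; includes rare variants so
#'   the minor-allele-count filter is exercised.
#' @param seed Seed for the (deterministic) metadata draws.
#' @return A tibble: `snp_id`, `chromosome`, `position`, `maf`, `role`
#'   (`"main_causal"`, `"background"` or `"null"`).
#' @export
snp_metadata <- function(causal_maf = c(0.30, 0.10, 0.25, 0.05, 0.20),
                         n_background = 100L,
                         n_null_per_chrom = 150L,
                         null_maf_range = c(0.01, 0.5),
                         seed = 1L) {
  stopifnot(length(causal_maf) == 5L)
  with_seed(sub_seed(seed, "snp_metadata"), {
    causal <- tibble::tibble(
      snp_id = sprintf("snp_c%02d", 1:5),
      chromosome = 1:5,
      position = as.integer(1e6 * (1:5) + 1234L),
      maf = causal_maf,
      role = "main_causal"
    )
    background <- tibble::tibble(
      snp_id = sprintf("snp_b%03d", seq_len(n_background)),
      chromosome = rep_len(1:20, n_background),
      position = as.integer(2e6 + 1e4 * seq_len(n_background)),
      maf = seq(0.1, 0.5, length.out = n_background),
      role = "background"
    )
    null <- purrr::map_dfr(c(21L, 22L), function(chr) {
      tibble::tibble(
        snp_id = sprintf("snp_n%d_%03d", chr, seq_len(n_null_per_chrom)),
        chromosome = chr,
        position = sort(sample.int(5e7, n_null_per_chrom)),
        maf = stats::runif(n_null_per_chrom, null_maf_range[1], null_maf_range[2]),
        role = "null"
      )
    })
    dplyr::bind_rows(causal, background, null)
  })
}

#' Simulate SNP dosages on a pedigree
#'
#' Founders are drawn under Hardy-Weinberg equilibrium at each SNP's minor
#' allele frequency; offspring receive one gamete from each parent, with the
#' transmitted allele drawn uniformly from the parent's two alleles (a parent
#' with dosage d transmits the minor allele with probability d/2). Loci are
#' unlinked and independent.
#'
#' @param pedigree Pedigree tibble ([build_pedigrees()]).
#' @param snp_metadata Marker tibble ([snp_metadata()]); `maf` must lie in
#'   (0, 0.5].
#' @param seed Integer seed.
#' @return A `gxm_genotypes` list: `dosages` (individuals x SNPs integer
#'   matrix, dimnames set) and `map` (the metadata tibble).
#' @export
simulate_genotypes <- function(pedigree, snp_metadata, seed = 1L) {
  validate_pedigree(pedigree)
  if (any(snp_metadata$maf <= 0 | snp_metadata$maf > 0.5)) {
    stop("SNP minor allele frequencies must lie in (0, 0.5].", call. = FALSE)
  }
  ord <- pedigree_order(pedigree)
  ped <- pedigree[ord, ]
  n <- nrow(ped)
  p <- nrow(snp_metadata)
  fa <- match(ped$father_id, ped$individual_id)
  mo <- match(ped$mother_id, ped$individual_id)
  founder <- is.na(fa)

  with_seed(sub_seed(seed, "genotypes"), {
    dos <- matrix(0L, n, p,
                  dimnames = list(ped$individual_id, snp_metadata$snp_id))
    nf <- sum(founder)
    dos[founder, ] <- matrix(
      stats::rbinom(nf * p, 2L, rep(snp_metadata$maf, each = nf)), nf, p
    )
    kids <- which(!founder)  # topological order: parents already filled
    for (i in kids) {
      pat <- stats::rbinom(p, 1L, dos[fa[i], ] / 2)
      mat <- stats::rbinom(p, 1L, dos[mo[i], ] / 2)
      dos[i, ] <- pat + mat
    }
    # restore the caller's row order
    dos <- dos[match(pedigree$individual_id, rownames(dos)), , drop = FALSE]
    structure(list(dosages = dos, map = snp_metadata),
              class = "gxm_genotypes")
  })
}

#' @export
print.gxm_genotypes <- function(x, ...) {
  cat("<gxm_genotypes> ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " SNPs (",
      sum(x$map$role == "main_causal"), " causal, ",
      sum(x$map$role == "background"), " background, ",
      sum(x$map$role == "null"), " null)\n", sep = "")
  invisible(x)
}
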