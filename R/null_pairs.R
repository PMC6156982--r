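#' Pair null-chromosome SNPs with downstream CpGs
#'
#' Builds the empirical-null marker pairs: on each effect-free chromosome,
#' SNPs are processed in ascending position and each is paired with the
#' nearest CpG at a strictly higher base-pair position that has not already
#' been used; SNPs with no available downstream CpG stay unpaired. The rule
#' is deterministic and never reuses a CpG, so the number of pairs is at most
#' `min(#SNPs, #CpGs)` per chromosome and typically far fewer than the number
#' of SNPs.
#'
#' @param snp_map,cpg_map Marker metadata tibbles with `chromosome` and
#'   `position` columns (`snp_id` / `cpg_id`).
#' @param null_chromosomes Chromosomes flagged effect-free (default 21:22).
#' @param max_distance Optional cap (bp) on the SNP-to-CpG distance; `Inf`
#'   (default) disables it.
#' @return Tibble: `chromosome`, `snp_id`, `snp_pos`, `cpg_id`, `cpg_pos`.
#' @export
#' @examples
#' snps <- tibble::tibble(snp_id = c("s1", "s2"), chromosome = 21,
#'                        position = c(100, 500))
#' cpgs <- tibble::tibble(cpg_id = c("c1", "c2"), chromosome = 21,
#'                        position = c(200, 600))
#' pair_null_markers(snps, cpgs)
pair_null_markers <- function(snp_map, cpg_map, null_chromosomes = 21:22,
                              max_distance = Inf) {
  out <- purrr::map_dfr(null_chromosomes, function(chr) {
    snps <- dplyr::arrange(
      dplyr::filter(snp_map, .data$chromosome == chr), .data$position)
    cpgs <- dplyr::arrange(
      dplyr::filter(cpg_map, .data$chromosome == chr), .data$position)
    if (!nrow(snps) || !nrow(cpgs)) return(NULL)
    j <- 1L
    m <- nrow(cpgs)
    res <- vector("list", nrow(snps))
    for (i in seq_len(nrow(snps))) {
      while (j <= m && cpgs$position[j] <= snps$position[i]) j <- j + 1L
      if (j > m) break
      if (cpgs$position[j] - snps$position[i] <= max_distance) {
        res[[i]] <- tibble::tibble(
          chromosome = chr,
          snp_id = snps$snp_id[i], snp_pos = snps$position[i],
          cpg_id = cpgs$cpg_id[j], cpg_pos = cpgs$position[j]
        )
        j <- j + 1L
      }
    }
    dplyr::bind_rows(res)
  })
  if (!nrow(out)) {
    out <- tibble::tibble(chromosome = integer(), snp_id = character(),
                          snp_pos = integer(), cpg_id = character(),
                          cpg_pos = integer())
  }
  out
}

#' Minor allele count of a dosage vector
#'
#' `MAC = min(sum(dosage), 2n - sum(dosage))`: the count of whichever allele
#' is rarer in the analyzed sample.
#'
#' @param dosages Vector with entries in \{0, 1, 2\}.
#' @return A single number.
#' @export
#' @examples
#' minor_allele_count(c(0, 1, 2, 0))
minor_allele_count <- function(dosages) {
  if (anyNA(dosages) || !all(dosages %in% c(0, 1, 2))) {
    stop("Dosages must be 0, 1 or 2 with no missing values.", call. = FALSE)
  }
  s <- sum(dosages)
  min(s, 2 * length(dosages) - s)
}

#' Filter null pairs by minor allele count
#'
#' Keeps pairs whose SNP has `MAC` strictly greater than `threshold`
#' (matching the strict "MAC > 50" convention), and records each pair's MAC
#' in the output.
#'
#' @param pairs Pair tibble from [pair_null_markers()].
#' @param genotypes `gxm_genotypes` holding the SNP dosages.
#' @param threshold Non-negative MAC threshold (default 50).
#' @return The filtered pair tibble with a `mac` column added.
#' @export
apply_mac_filter <- function(pairs, genotypes, threshold = 50) {
  stopifnot(threshold >= 0)
  if (!nrow(pairs)) return(dplyr::mutate(pairs, mac = numeric(0)))
  mac <- vapply(pairs$snp_id,
                function(id) minor_allele_count(genotypes$dosages[, id]),
                numeric(1))
  dplyr::filter(dplyr::mutate(pairs, mac = unname(mac)),
                .data$mac > threshold)
}
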