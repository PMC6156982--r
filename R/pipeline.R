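#' Run configuration for the end-to-end pipeline
#'
#' Bundles every knob of the replicate-generation / fitting / evaluation
#' pipeline. The defaults reproduce the emulated study design: 200
#' replicates of 680 individuals, models 1a-2b, alpha 0.05 and a
#' minor-allele-count filter at 50 (the test-scale defaults here use fewer
#' replicates; pass `n_replicates = 200` for the full design).
#'
#' @param n_replicates Number of replicates (default 10 for interactive use).
#' @param n_individuals Individuals per replicate (default 680).
#' @param seed Study seed.
#' @param models Models to fit (subset of `c("1a","1b","2a","2b")`).
#' @param methods Association methods (subset of `c("glm", "mixed")`).
#' @param alpha Significance level (default 0.05).
#' @param mac_threshold Minor-allele-count filter for null pairs (default 50).
#' @param n_null_pairs Number of null SNP-CpG pairs tested per replicate
#'   (default 100; `Inf` for all available).
#' @param effects_overrides Named list passed to [effect_config()].
#' @return A `gxm_config` list.
#' @export
run_config <- function(n_replicates = 10L, n_individuals = 680L, seed = 1L,
                       models = c("1a", "1b"), methods = c("glm", "mixed"),
                       alpha = 0.05, mac_threshold = 50,
                       n_null_pairs = 100L, effects_overrides = list()) {
  stopifnot(all(models %in% c("1a", "1b", "2a", "2b")),
            all(methods %in% c("glm", "mixed")),
            alpha > 0, alpha < 1, mac_threshold >= 0)
  structure(list(n_replicates = as.integer(n_replicates),
                 n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed), models = models, methods = methods,
                 alpha = alpha, mac_threshold = mac_threshold,
                 n_null_pairs = n_null_pairs,
                 effects_overrides = effects_overrides),
            class = "gxm_config")
}

#' Run the full simulation-and-analysis pipeline
#'
#' Generates the study, runs the requested model x method grid on the causal
#' pairs, the background SNPs and the null pairs on chromosomes 21/22;
#' aggregates power / Type-I tables; and writes every table plus a
#' machine-readable manifest to `out_dir`. Re-running with the same config
#' and seed reproduces the tables byte for byte; per-replicate result files
#' act as checkpoints and are reused when `resume = TRUE`.
#'
#' @details Background SNPs carry tiny main effects but have no interacting
#' CpG of their own; they are tested against the first causal CpG, so their
#' pooled interaction category probes how often small real main effects leak
#' into the interaction term.
#'
#' @param config A `gxm_config` from [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param resume Reuse per-replicate checkpoint files if present.
#' @param quiet Suppress per-replicate progress messages.
#' @return Invisibly, a list with `results` (long tibble), `power_table`,
#'   `manifest`, and the `study`.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "gxm_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ckpt_dir <- file.path(out_dir, "replicates")
  dir.create(ckpt_dir, showWarnings = FALSE)

  study <- do.call(simulate_study,
                   c(list(n_individuals = config$n_individuals,
                          seed = config$seed),
                     config$effects_overrides))
  causal <- dplyr::filter(study$snp_map, .data$role == "main_causal")
  causal_cpg <- study$cpg_map[match(causal$snp_id, study$cpg_map$paired_snp), ]
  causal_pairs <- tibble::tibble(
    category = paste(causal_cpg$cpg_id, causal$snp_id, sep = " * "),
    snp_id = causal$snp_id, cpg_id = causal_cpg$cpg_id
  )
  bg <- dplyr::filter(study$snp_map, .data$role == "background")
  bg_pairs <- tibble::tibble(category = "background_snps",
                             snp_id = bg$snp_id,
                             cpg_id = causal_cpg$cpg_id[1])
  null_pairs <- pair_null_markers(study$snp_map, study$cpg_map)
  if (is.finite(config$n_null_pairs) &&
      nrow(null_pairs) > config$n_null_pairs) {
    null_pairs <- null_pairs[seq_len(config$n_null_pairs), ]
  }
  null_tbl <- tibble::tibble(category = "null_snp_interactions",
                             snp_id = null_pairs$snp_id,
                             cpg_id = null_pairs$cpg_id)
  pairs <- dplyr::bind_rows(causal_pairs, bg_pairs, null_tbl)

  res <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    ckpt <- file.path(ckpt_dir, sprintf("replicate_%03d.tsv", r))
    if (resume && file.exists(ckpt)) {
      res[[r]] <- read_results(ckpt)
      next
    }
    if (!quiet) message("replicate ", r, "/", config$n_replicates)
    rep_data <- simulate_replicate(study, r)
    out <- run_pair_tests(pairs, study$genotypes, rep_data$methylation,
                          rep_data$traits, models = config$models,
                          methods = config$methods, replicate = r)
    nc <- dplyr::filter(out, !.data$converged & .data$applicable)
    if (nrow(nc) && !quiet) {
      warning("Replicate ", r, ": ", nrow(nc),
              " non-converged fit(s): ",
              paste(utils::head(paste(nc$snp_id, nc$cpg_id), 3),
                    collapse = "; "), call. = FALSE)
    }
    write_results(out, ckpt)
    res[[r]] <- read_results(ckpt)
  }
  results <- dplyr::bind_rows(res)

  # MAC-filtered null category (MAC is replicate-invariant: fixed genotypes)
  null_keep <- apply_mac_filter(null_pairs, study$genotypes,
                                config$mac_threshold)
  filtered <- results |>
    dplyr::filter(.data$category == "null_snp_interactions",
                  .data$snp_id %in% null_keep$snp_id) |>
    dplyr::mutate(category = sprintf("null_snp_interactions (w/MAC>%g)",
                                     config$mac_threshold))
  power_table <- summarize_replicates(dplyr::bind_rows(results, filtered),
                                      alpha = config$alpha)
  power_table <- dplyr::mutate(power_table,
                               threshold = sprintf("p<%g", config$alpha))

  manifest <- list(
    package = "gxmeth",
    version = as.character(utils::packageVersion("gxmeth")),
    config = unclass(config),
    replicate_seeds = vapply(seq_len(config$n_replicates), function(r)
      sub_seed(config$seed, "phenotypes", r), integer(1)),
    n_causal_pairs = nrow(causal_pairs),
    n_null_pairs = nrow(null_tbl),
    n_null_pairs_mac = nrow(null_keep)
  )
  write_results(results, file.path(out_dir, "results.tsv"))
  write_results(power_table, file.path(out_dir, "power_table.tsv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, power_table = power_table,
                 manifest = manifest, study = study))
}
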