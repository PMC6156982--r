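#' Derive the analysis traits from raw phenotypes and methylation
#'
#' Computes the traits the interaction models are built on:
#' `Pre` = mean of log(TG1) and log(TG2), `Post` = mean of log(TG3) and
#' log(TG4), `delta_tg = Post - Pre`, and per-CpG `delta_cpg` = visit-4 minus
#' visit-2 beta-value. Natural logarithms are used throughout.
#'
#' @param phenotypes Phenotype tibble with positive `TG1`-`TG4`, `age`, `sex`.
#' @param methylation Optional `gxm_methylation`; when supplied, the
#'   `delta_cpg` matrix is attached.
#' @return A `gxm_traits` tibble: `individual_id`, `family_id`, `pre`,
#'   `post`, `delta_tg`, `age`, `sex`; attribute `delta_cpg` holds the
#'   individuals x CpGs difference matrix when methylation is given.
#' @export
#' @examples
#' ph <- tibble::tibble(individual_id = "a", family_id = "f",
#'                      TG1 = exp(2), TG2 = exp(2), TG3 = exp(3),
#'                      TG4 = exp(3), age = 40, sex = "male")
#' derive_traits(ph)
derive_traits <- function(phenotypes, methylation = NULL) {
  tg <- as.matrix(phenotypes[, c("TG1", "TG2", "TG3", "TG4")])
  bad <- which(apply(tg <= 0 | !is.finite(tg), 1, any))
  if (length(bad)) {
    stop("Non-positive TG values for individual(s): ",
         paste(phenotypes$individual_id[utils::head(bad, 5)], collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    individual_id = phenotypes$individual_id,
    family_id = phenotypes$family_id,
    pre = (log(phenotypes$TG1) + log(phenotypes$TG2)) / 2,
    post = (log(phenotypes$TG3) + log(phenotypes$TG4)) / 2,
    age = phenotypes$age,
    sex = phenotypes$sex
  )
  out$delta_tg <- out$post - out$pre
  if (!is.null(methylation)) {
    attr(out, "delta_cpg") <- methylation$beta_visit4 - methylation$beta_visit2
  }
  class(out) <- c("gxm_traits", class(out))
  out
}

#' Build the design matrix for one interaction model
#'
#' Constructs the regressor layout of the four model parameterizations:
#'
#' * **1a** (generating model): response `post`; columns intercept, `snp`,
#'   `meth` = (1 - CpG beta-value), `snp_meth` = snp x (1 - CpG), `age`,
#'   `age2`, `sex`, `pre` (8 columns).
#' * **1b** (reduced): as 1a without the SNP and methylation main effects
#'   (6 columns).
#' * **2a**: response `delta_tg`; columns intercept, `snp`,
#'   `meth` = delta-CpG (visit 4 - visit 2), `snp_meth`, `age`, `age2`,
#'   `sex` (7 columns; no `pre`).
#' * **2b** (reduced 2a): intercept, `snp_meth`, `age`, `age2`, `sex`
#'   (5 columns).
#'
#' Methylation enters models 1a/1b as `1 - CpG` because lower methylation
#' means higher expression of the modified gene; models 2a/2b use the
#' longitudinal methylation change instead. `age2` is uncentred age squared;
#' sex is coded 0 = female, 1 = male.
#'
#' @param model_id One of `"1a"`, `"1b"`, `"2a"`, `"2b"`.
#' @param snp_dosage Numeric dosage vector (0/1/2) for the SNP under test.
#' @param cpg_values For models 1a/1b, the CpG beta-values (the visit is the
#'   caller's choice; the post-treatment visit by default in the pipeline);
#'   for 2a/2b the per-individual delta-CpG values.
#' @param traits `gxm_traits` tibble from [derive_traits()].
#' @return A `gxm_design` list: `x` (named numeric matrix), `response`
#'   (numeric), `response_label`, `model_id`, `family_id`.
#' @export
build_design <- function(model_id, snp_dosage, cpg_values, traits) {
  model_id <- as.character(model_id)
  if (!model_id %in% c("1a", "1b", "2a", "2b")) {
    stop("Unknown model id '", model_id, "'; expected 1a, 1b, 2a or 2b.",
         call. = FALSE)
  }
  n <- nrow(traits)
  stopifnot(length(snp_dosage) == n, length(cpg_values) == n)
  sexm <- as.numeric(traits$sex == "male")
  meth <- if (model_id %in% c("1a", "1b")) 1 - cpg_values else cpg_values
  snp <- as.numeric(snp_dosage)
  base <- cbind(intercept = 1, age = traits$age, age2 = traits$age^2,
                sex = sexm)
  x <- switch(model_id,
    "1a" = cbind(intercept = 1, snp = snp, meth = meth,
                 snp_meth = snp * meth, age = traits$age,
                 age2 = traits$age^2, sex = sexm, pre = traits$pre),
    "1b" = cbind(intercept = 1, snp_meth = snp * meth, age = traits$age,
                 age2 = traits$age^2, sex = sexm, pre = traits$pre),
    "2a" = cbind(intercept = 1, snp = snp, meth = meth,
                 snp_meth = snp * meth, age = traits$age,
                 age2 = traits$age^2, sex = sexm),
    "2b" = cbind(intercept = 1, snp_meth = snp * meth, age = traits$age,
                 age2 = traits$age^2, sex = sexm)
  )
  response_label <- if (model_id %in% c("1a", "1b")) "post" else "delta_tg"
  structure(list(
    x = x,
    response = traits[[response_label]],
    response_label = response_label,
    model_id = model_id,
    family_id = traits$family_id
  ), class = "gxm_design")
}

#' @export
print.gxm_design <- function(x, ...) {
  cat("<gxm_design> model ", x$model_id, ": ", x$response_label, " ~ ",
      paste(colnames(x$x), collapse = " + "), "\n", sep = "")
  invisible(x)
}
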