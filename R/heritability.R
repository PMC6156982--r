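#' Polygenic narrow-sense heritability by kinship REML
#'
#' Fits the variance-component model `y = X beta + g + e` with
#' `cov(g) = 2 * Phi * sigma2_g` and i.i.d. residuals by restricted maximum
#' likelihood. After a single eigendecomposition of `2 * Phi`, the model is
#' rotated to independent observations with variances
#' `sigma2_total * (h2 * lambda_i + 1 - h2)`; the total variance is profiled
#' out in closed form and the restricted likelihood is maximized over the
#' single parameter `h2` in [0, 1] by golden-section search
#' ([stats::optimize()]) with explicit boundary checks. Boundary estimates
#' (h2 of exactly 0 or 1) are flagged, not errors.
#'
#' @param response Numeric response vector (e.g. the Post trait).
#' @param covariates Numeric matrix/data frame of covariates (an intercept is
#'   added automatically); `NULL` for intercept only.
#' @param kinship Kinship matrix Phi (positive semi-definite after doubling).
#' @param kinship_eigen Optional precomputed `eigen(2 * kinship)` to reuse
#'   across replicates on a fixed pedigree.
#' @return A `gxm_h2` list: `h2`, `sigma2_g`, `sigma2_e`, `loglik` (restricted),
#'   `boundary`, `converged`, `n`.
#' @export
polygenic_h2 <- function(response, covariates, kinship,
                         kinship_eigen = NULL) {
  y <- as.numeric(response)
  n <- length(y)
  if (n < 30) stop("At least 30 individuals are required.", call. = FALSE)
  X <- h2_design(covariates, n)
  eg <- kinship_eigen %||% eigen(2 * kinship, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values))) {
    stop("2 * kinship must be positive semi-definite.", call. = FALSE)
  }
  lambda <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)
  p <- ncol(Xt)

  crit <- function(h2) reml_profile(h2, yt, Xt, lambda, n, p)$loglik
  opt <- stats::optimize(crit, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  vals <- c(opt$objective, crit(0), crit(1))
  h2 <- cand[which.max(vals)]
  prof <- reml_profile(h2, yt, Xt, lambda, n, p)
  structure(list(
    h2 = h2,
    sigma2_g = h2 * prof$sigma2,
    sigma2_e = (1 - h2) * prof$sigma2,
    loglik = prof$loglik,
    boundary = h2 < 1e-6 || h2 > 1 - 1e-6,
    converged = TRUE,
    n = n
  ), class = "gxm_h2")
}

# restricted log-likelihood profiled over the total variance, in the rotated
# basis where the covariance is diag(h2 * lambda + 1 - h2) * sigma2
reml_profile <- function(h2, yt, Xt, lambda, n, p) {
  w <- h2 * lambda + (1 - h2)
  w <- pmax(w, 1e-12)
  sw <- sqrt(w)
  Xw <- Xt / sw
  yw <- yt / sw
  qr_x <- qr(Xw)
  beta <- qr.coef(qr_x, yw)
  rss <- sum((yw - Xw %*% beta)^2)
  sigma2 <- rss / (n - p)
  xtwx_logdet <- 2 * sum(log(abs(diag(qr.R(qr_x)))))
  loglik <- -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) +
                      sum(log(w)) + xtwx_logdet)
  list(loglik = loglik, sigma2 = sigma2, beta = beta, qr_x = qr_x, w = w)
}

# full GLS fit under the kinship model at the REML optimum; used by the
# kinship variant of the mixed-model association test
reml_kinship <- function(y, X, kinship, kinship_eigen = NULL) {
  n <- length(y)
  eg <- kinship_eigen %||% eigen(2 * kinship, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)
  p <- ncol(Xt)
  crit <- function(h2) reml_profile(h2, yt, Xt, lambda, n, p)$loglik
  opt <- stats::optimize(crit, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  vals <- c(opt$objective, crit(0), crit(1))
  h2 <- cand[which.max(vals)]
  prof <- reml_profile(h2, yt, Xt, lambda, n, p)
  xtwx_inv <- chol2inv(qr.R(prof$qr_x))
  se <- sqrt(prof$sigma2 * diag(xtwx_inv))
  beta <- as.numeric(prof$beta)
  names(beta) <- names(se) <- colnames(X)
  list(beta = beta, se_beta = se, h2 = h2,
       sigma2_g = h2 * prof$sigma2, sigma2_e = (1 - h2) * prof$sigma2,
       loglik = prof$loglik, converged = TRUE)
}

h2_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (!"intercept" %in% colnames(X)) {
    X <- cbind(intercept = 1, X)
  }
  stopifnot(nrow(X) == n)
  X
}

#' @export
print.gxm_h2 <- function(x, ...) {
  cat("<gxm_h2> h2 = ", signif(x$h2, 4),
      " (sigma2_g = ", signif(x$sigma2_g, 4),
      ", sigma2_e = ", signif(x$sigma2_e, 4), ")",
      if (x$boundary) "  [boundary]", "\n", sep = "")
  invisible(x)
}

#' Per-SNP variance contribution b2
#'
#' Squared standardized regression coefficient of a single SNP: the response
#' is residualized on the covariates, residuals and dosage are z-scored
#' (sample sd, n - 1 denominator), and `b2` is the squared slope of the
#' standardized regression - algebraically the squared Pearson correlation
#' between standardized residuals and standardized dosage, an approximate
#' per-locus additive variance fraction.
#'
#' @param response Numeric response (e.g. Post).
#' @param covariates Covariate matrix/data frame (intercept added), or `NULL`.
#' @param dosage Dosage vector for one SNP.
#' @return A list: `b2`, `beta_std` (signed standardized slope),
#'   `applicable` (`FALSE` for a monomorphic SNP, with `NA` estimates).
#' @export
snp_b2 <- function(response, covariates, dosage) {
  y <- as.numeric(response)
  X <- h2_design(covariates, length(y))
  if (stats::var(dosage) < .Machine$double.eps * 100) {
    return(list(b2 = NA_real_, beta_std = NA_real_, applicable = FALSE))
  }
  res <- stats::lm.fit(X, y)$residuals
  zr <- (res - mean(res)) / stats::sd(res)
  zd <- (dosage - mean(dosage)) / stats::sd(dosage)
  slope <- sum(zr * zd) / sum(zd * zd)
  list(b2 = slope^2, beta_std = slope, applicable = TRUE)
}

#' Heritability and b2 across simulated replicates
#'
#' Convenience runner reproducing the replicate-level heritability table:
#' for each replicate, the polygenic h2 of Post (covariates age, age squared,
#' sex) and the per-causal-SNP b2 (covariates additionally including Pre).
#' The kinship eigendecomposition is computed once and reused.
#'
#' @param study `gxm_study`.
#' @param n_replicates Number of replicates to draw.
#' @param snp_ids SNPs for b2 (default: the causal SNPs).
#' @return A list of tibbles: `h2` (replicate, h2, sigma2_g, sigma2_e,
#'   boundary) and `b2` (replicate, snp_id, b2).
#' @export
estimate_heritability_replicates <- function(study, n_replicates = 50L,
                                             snp_ids = NULL) {
  eg <- eigen(2 * study$kinship, symmetric = TRUE)
  ped <- study$pedigree
  sexm <- as.numeric(ped$sex == "male")
  cov_h2 <- cbind(age = ped$age, age2 = ped$age^2, sex = sexm)
  if (is.null(snp_ids)) {
    snp_ids <- study$snp_map$snp_id[study$snp_map$role == "main_causal"]
  }
  h2_rows <- vector("list", n_replicates)
  b2_rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_data <- simulate_replicate(study, r)
    tr <- rep_data$traits
    fit <- polygenic_h2(tr$post, cov_h2, study$kinship, kinship_eigen = eg)
    h2_rows[[r]] <- tibble::tibble(replicate = r, h2 = fit$h2,
                                   sigma2_g = fit$sigma2_g,
                                   sigma2_e = fit$sigma2_e,
                                   boundary = fit$boundary)
    cov_b2 <- cbind(cov_h2, pre = tr$pre)
    b2_rows[[r]] <- purrr::map_dfr(snp_ids, function(id) {
      est <- snp_b2(tr$post, cov_b2, study$genotypes$dosages[, id])
      tibble::tibble(replicate = r, snp_id = id, b2 = est$b2)
    })
  }
  list(h2 = dplyr::bind_rows(h2_rows), b2 = dplyr::bind_rows(b2_rows))
}

#' Summarize replicate estimates in a heritability-table layout
#'
#' @param estimates Tibble with an estimate column and optional grouping
#'   column (e.g. `snp_id`).
#' @param value Name of the estimate column.
#' @param by Optional grouping column name.
#' @return Tibble with mean, median and SD of the estimates.
#' @export
summarize_estimates <- function(estimates, value, by = NULL) {
  g <- if (is.null(by)) estimates else
    dplyr::group_by(estimates, dplyr::across(dplyr::all_of(by)))
  dplyr::summarise(
    g,
    mean = mean(.data[[value]], na.rm = TRUE),
    median = stats::median(.data[[value]], na.rm = TRUE),
    sd = stats::sd(.data[[value]], na.rm = TRUE),
    n = sum(!is.na(.data[[value]])),
    .groups = "drop"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
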