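# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are built once per test run and cached in this
# environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# one trio: two founders and a child
trio_pedigree <- function() {
  tibble::tibble(
    family_id = "F1",
    individual_id = c("dad", "mum", "kid"),
    father_id = c(NA, NA, "dad"),
    mother_id = c(NA, NA, "mum"),
    sex = c("male", "female", "female"),
    age = c(50, 48, 22)
  )
}

# three generations, 8 members: founders gp1 x gp2 -> p1, aunt;
# p1 x p2 (founder) -> c1, c2; aunt x a2 (founder) -> cc1
three_gen_pedigree <- function() {
  tibble::tibble(
    family_id = "F1",
    individual_id = c("gp1", "gp2", "p1", "aunt", "p2", "c1", "c2", "cc1"),
    father_id = c(NA, NA, "gp1", "gp1", NA, "p1", "p1", NA),
    mother_id = c(NA, NA, "gp2", "gp2", NA, "p2", "p2", NA),
    sex = c("male", "female", "male", "female", "female",
            "male", "female", "male"),
    age = c(75, 73, 50, 48, 49, 25, 23, 24)
  )
}

# Monte-Carlo gene-dropping kinship oracle: founders get unique allele
# labels, offspring inherit one allele per parent uniformly; kinship(i, j)
# is the probability a random allele of i is identical by descent to a
# random allele of j, averaged over drops and allele picks.
gene_drop_kinship <- function(pedigree, n_drops = 20000, seed = 1) {
  set.seed(seed)
  ids <- pedigree$individual_id
  n <- length(ids)
  fa <- match(pedigree$father_id, ids)
  mo <- match(pedigree$mother_id, ids)
  a1 <- matrix(0L, n_drops, n)
  a2 <- matrix(0L, n_drops, n)
  next_allele <- 1L
  for (i in order(is.na(fa), decreasing = TRUE)) {
    if (is.na(fa[i])) {
      a1[, i] <- next_allele
      a2[, i] <- next_allele + 1L
      next_allele <- next_allele + 2L
    }
  }
  # parents-first pass (assumes parents precede children once founders done)
  done <- is.na(fa)
  while (!all(done)) {
    for (i in which(!done)) {
      if (done[fa[i]] && done[mo[i]]) {
        pick1 <- stats::runif(n_drops) < 0.5
        pick2 <- stats::runif(n_drops) < 0.5
        a1[, i] <- ifelse(pick1, a1[, fa[i]], a2[, fa[i]])
        a2[, i] <- ifelse(pick2, a1[, mo[i]], a2[, mo[i]])
        done[i] <- TRUE
      }
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ibd <- (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
        (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])
      phi[i, j] <- mean(ibd) / 4
    }
  }
  phi
}

# Dense restricted log-likelihood for arbitrary covariance V (grid oracles);
# same convention as the package's profiled criterion.
reml_loglik_dense <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(
    -0.5 * (determinant(V, logarithm = TRUE)$modulus +
              determinant(XtVX, logarithm = TRUE)$modulus +
              t(r) %*% Vi %*% r + (n - p) * log(2 * pi))
  )
}

# Brute-force re-implementation of the null pairing rule: ascending SNPs,
# nearest strictly-downstream unused CpG, scanning the full CpG list.
brute_force_pairs <- function(snps, cpgs) {
  used <- rep(FALSE, nrow(cpgs))
  out <- list()
  for (i in order(snps$position)) {
    cand <- which(!used & cpgs$position > snps$position[i])
    if (!length(cand)) next
    j <- cand[which.min(cpgs$position[cand] - snps$position[i])]
    used[j] <- TRUE
    out[[length(out) + 1]] <- data.frame(snp_id = snps$snp_id[i],
                                         cpg_id = cpgs$cpg_id[j])
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(snp_id = character(), cpg_id = character())
}

# small default-configuration study reused across test files
small_study <- function() {
  fixture("small_study", simulate_study(n_individuals = 240, seed = 101))
}

full_study <- function() {
  fixture("full_study", simulate_study(n_individuals = 680, seed = 42))
}

# effects object with every systematic term switched off: pure residual
null_effects <- function(effects, sigma2_e = NULL) {
  effects$beta1[] <- 0
  effects$beta2[] <- 0
  effects$beta3[] <- 0
  effects$beta_background[] <- 0
  effects$gamma_pre <- 0
  effects$beta_age <- 0
  effects$beta_age2 <- 0
  effects$beta_sex <- 0
  effects$sigma2_poly <- 0
  if (!is.null(sigma2_e)) {
    effects$sigma2_e <- sigma2_e
    effects$sigma2_visit <- 0
  }
  effects
}
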