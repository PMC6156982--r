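test_that("pedigrees have the requested size and nuclear structure", {
  ped <- build_pedigrees(680, seed = 3)
  expect_equal(nrow(ped), 680)
  expect_equal(anyDuplicated(ped$individual_id), 0L)
  # every family is nuclear: exactly two founders, children point to them
  by_fam <- split(ped, ped$family_id)
  for (fam in by_fam) {
    founders <- fam[is.na(fam$father_id), ]
    kids <- fam[!is.na(fam$father_id), ]
    expect_lte(nrow(founders), 2L)
    if (nrow(kids)) {
      expect_equal(nrow(founders), 2L)
      expect_setequal(unique(kids$father_id),
                      founders$individual_id[founders$sex == "male"])
      expect_setequal(unique(kids$mother_id),
                      founders$individual_id[founders$sex == "female"])
    }
  }
  # a trio when asked for exactly three
  trio <- build_pedigrees(3, n_children_range = c(1, 1), seed = 1)
  expect_equal(nrow(trio), 3)
  expect_equal(sum(is.na(trio$father_id)), 2)
  kid <- trio[!is.na(trio$father_id), ]
  expect_true(kid$father_id %in% trio$individual_id)
})

test_that("pedigree generation is deterministic and validates input", {
  expect_identical(build_pedigrees(100, seed = 9), build_pedigrees(100, seed = 9))
  expect_false(identical(build_pedigrees(100, seed = 9),
                         build_pedigrees(100, seed = 10)))
  expect_error(build_pedigrees(0), "positive")
  expect_error(build_pedigrees(-5), "positive")
})

test_that("kinship matches hand-computed coefficients on known structures", {
  phi <- kinship_matrix(trio_pedigree())
  expect_equal(unname(diag(phi)), rep(0.5, 3))
  expect_equal(phi["dad", "mum"], 0)
  expect_equal(phi["dad", "kid"], 0.25)
  expect_equal(phi["mum", "kid"], 0.25)

  phi3 <- kinship_matrix(three_gen_pedigree())
  expect_equal(phi3["c1", "c2"], 0.25)      # full sibs
  expect_equal(phi3["gp1", "c1"], 0.125)    # grandparent-grandchild
  expect_equal(phi3["aunt", "c1"], 0.125)   # avuncular
  expect_equal(phi3["p2", "aunt"], 0)       # unrelated in-laws
  expect_true(isSymmetric(phi3))
  expect_true(all(phi3 >= 0 & phi3 <= 0.5))
  # 2 * Phi is a valid genetic covariance: positive semi-definite
  expect_gte(min(eigen(2 * phi3, symmetric = TRUE)$values), -1e-10)
  expect_error(kinship_matrix(dplyr::mutate(
    trio_pedigree(), father_id = c("kid", NA, "dad"),
    mother_id = c("mum", NA, "mum"))), "cycle|own ancestor")
})

test_that("offspring dosages are Mendelian-consistent with parents", {
  st <- small_study()
  ped <- st$pedigree
  dos <- st$genotypes$dosages
  kids <- which(!is.na(ped$father_id))
  fa <- match(ped$father_id, ped$individual_id)
  mo <- match(ped$mother_id, ped$individual_id)
  consistent <- function(child, f, m) {
    pat <- if (f == 0) 0 else if (f == 2) 1 else c(0, 1)
    mat <- if (m == 0) 0 else if (m == 2) 1 else c(0, 1)
    child %in% outer(pat, mat, `+`)
  }
  ok <- vapply(kids, function(i) {
    all(mapply(consistent, dos[i, ], dos[fa[i], ], dos[mo[i], ]))
  }, logical(1))
  expect_true(all(ok))
})

test_that("founder genotypes follow Hardy-Weinberg at the configured MAF", {
  founders <- tibble::tibble(
    family_id = paste0("F", 1:5000),
    individual_id = paste0("i", 1:5000),
    father_id = NA_character_, mother_id = NA_character_,
    sex = rep(c("male", "female"), 2500), age = 40
  )
  map <- tibble::tibble(snp_id = "s1", chromosome = 1L, position = 100L,
                        maf = 0.3, role = "null")
  g <- simulate_genotypes(founders, map, seed = 5)
  # mean dosage ~ Binomial(2, 0.3): expectation 0.6, SE sqrt(2*.3*.7/n)
  se <- sqrt(2 * 0.3 * 0.7 / 5000)
  expect_lt(abs(mean(g$dosages) - 0.6), 3 * se)
  expect_error(simulate_genotypes(founders,
                                  dplyr::mutate(map, maf = 0.7)), "0, 0.5")
  expect_error(simulate_genotypes(founders,
                                  dplyr::mutate(map, maf = 0)), "0, 0.5")
  expect_identical(simulate_genotypes(founders, map, seed = 5)$dosages,
                   g$dosages)
})

test_that("methylation values are valid beta-values with the configured law", {
  st <- small_study()
  meth <- simulate_methylation(st$pedigree, st$cpg_map, seed = 4)
  expect_true(all(meth$beta_visit2 >= 0 & meth$beta_visit2 <= 1))
  expect_true(all(meth$beta_visit4 >= 0 & meth$beta_visit4 <= 1))
  # perfectly correlated visits with no treatment shift are identical
  m2 <- simulate_methylation(st$pedigree, st$cpg_map, treatment_effect = 0,
                             rho = 1, seed = 4)
  expect_equal(m2$beta_visit2, m2$beta_visit4)
  # marginal mean: n x m draws at mean 0.6, concentration 10
  big_ped <- tibble::tibble(
    family_id = paste0("F", 1:10000), individual_id = paste0("i", 1:10000),
    father_id = NA_character_, mother_id = NA_character_,
    sex = "female", age = 40)
  map1 <- tibble::tibble(cpg_id = "c1", chromosome = 1L, position = 1L,
                         mean_beta = 0.6, concentration = 10,
                         paired_snp = NA_character_)
  m3 <- simulate_methylation(big_ped, map1, seed = 8)
  se <- sqrt(0.6 * 0.4 / 11 / 10000)
  expect_lt(abs(mean(m3$beta_visit2) - 0.6), 3 * se)
  expect_error(simulate_methylation(st$pedigree,
                                    dplyr::mutate(st$cpg_map, mean_beta = 1.2)),
               "\\(0, 1\\)")
})

test_that("null phenotypes have the configured residual variance", {
  st <- small_study()
  ef <- null_effects(st$effects, sigma2_e = 0.2)
  ph <- simulate_phenotypes(st$pedigree, st$genotypes,
                            simulate_methylation(st$pedigree, st$cpg_map,
                                                 seed = 2),
                            ef, st$kinship, seed = 31)
  post <- (log(ph$TG3) + log(ph$TG4)) / 2
  n <- length(post)
  # sample variance of iid normals: SE = sigma2 * sqrt(2 / (n - 1))
  se <- 0.2 * sqrt(2 / (n - 1))
  expect_lt(abs(var(post) - 0.2), 3 * se)
})

test_that("an interaction-only locus explains its analytic variance share", {
  st <- small_study()
  ef <- null_effects(st$effects, sigma2_e = 0.1)
  ef$beta3[1] <- 0.4
  reps <- purrr::map(1:20, function(r) {
    meth <- simulate_methylation(st$pedigree, st$cpg_map, seed = 400 + r)
    ph <- simulate_phenotypes(st$pedigree, st$genotypes, meth, ef,
                              st$kinship, seed = 500 + r)
    post <- (log(ph$TG3) + log(ph$TG4)) / 2
    inter <- st$genotypes$dosages[, ef$snp_id[1]] *
      (1 - meth$beta_visit4[, ef$cpg_id[1]])
    c(var_post = var(post), var_inter = var(inter))
  })
  reps <- do.call(rbind, reps)
  # Var(Post) = beta3^2 Var(SNP (1 - CpG)) + sigma2_e
  expected <- 0.4^2 * mean(reps[, "var_inter"]) + 0.1
  observed <- mean(reps[, "var_post"])
  se <- sd(reps[, "var_post"]) / sqrt(nrow(reps))
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("polygenic variance makes siblings more alike than strangers", {
  st <- small_study()
  ef <- null_effects(st$effects, sigma2_e = 0.05)
  ef$sigma2_poly <- 0.2
  ped <- st$pedigree
  sib_pairs <- dplyr::filter(
    tidyr::crossing(i = seq_len(nrow(ped)), j = seq_len(nrow(ped))),
    .data$i < .data$j)
  fa <- ped$father_id
  is_sib <- !is.na(fa[sib_pairs$i]) & !is.na(fa[sib_pairs$j]) &
    fa[sib_pairs$i] == fa[sib_pairs$j]
  same_fam <- ped$family_id[sib_pairs$i] == ped$family_id[sib_pairs$j]
  sibs <- sib_pairs[is_sib, ]
  strangers <- sib_pairs[!same_fam, ][seq_len(2000), ]
  cors <- purrr::map(1:30, function(r) {
    meth <- simulate_methylation(ped, st$cpg_map, seed = 600 + r)
    ph <- simulate_phenotypes(ped, st$genotypes, meth, ef, st$kinship,
                              seed = 700 + r)
    post <- (log(ph$TG3) + log(ph$TG4)) / 2
    c(sib = cor(post[sibs$i], post[sibs$j]),
      str = cor(post[strangers$i], post[strangers$j]))
  })
  cors <- do.call(rbind, cors)
  expect_gt(mean(cors[, "sib"]), mean(cors[, "str"]) + 0.1)
})

test_that("the whole generator is deterministic under a fixed seed", {
  a <- simulate_study(n_individuals = 60, seed = 77)
  b <- simulate_study(n_individuals = 60, seed = 77)
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  ra <- simulate_replicate(a, 2)
  rb <- simulate_replicate(b, 2)
  expect_identical(ra$phenotypes, rb$phenotypes)
  expect_identical(ra$methylation$beta_visit4, rb$methylation$beta_visit4)
  # different replicate index gives a different draw
  expect_false(identical(ra$phenotypes$TG3,
                         simulate_replicate(a, 3)$phenotypes$TG3))
})
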