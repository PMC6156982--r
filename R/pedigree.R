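#' Build a nuclear-family pedigree of a given total size
#'
#' Generates a sample of unrelated nuclear families (two unrelated founders
#' plus their children) until the requested number of individuals is reached;
#' the last family is truncated if needed, so the total is exact. This mirrors
#' the structure of family-based lipid studies in which treatment response is
#' measured on adults from many small pedigrees.
#'
#' @param n_individuals Total number of individuals (default 680).
#' @param n_children_range Integer range of children per family; the number of
#'   children is drawn uniformly from `n_children_range[1]:n_children_range[2]`
#'   (default 1:4, i.e. family sizes 3-6).
#' @param age_range_parents,age_range_children Age ranges (years) from which
#'   ages are drawn uniformly.
#' @param seed Integer seed; the pedigree is deterministic given the seed.
#' @return A tibble with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id` (`NA` for founders), `sex` (`"male"`/`"female"`) and `age`.
#' @export
#' @examples
#' ped <- build_pedigrees(680, seed = 1)
#' nrow(ped)
build_pedigrees <- function(n_individuals = 680L,
                            n_children_range = c(1L, 4L),
                            age_range_parents = c(45, 75),
                            age_range_children = c(20, 50),
                            seed = 1L) {
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L ||
      n_individuals < 1) {
    stop("`n_individuals` must be a positive integer.", call. = FALSE)
  }
  n_individuals <- as.integer(n_individuals)
  stopifnot(length(n_children_range) == 2L,
            n_children_range[1] >= 0L,
            n_children_range[2] >= n_children_range[1])

  with_seed(seed, {
    rows <- list()
    total <- 0L
    fam <- 0L
    while (total < n_individuals) {
      fam <- fam + 1L
      sizes <- seq(n_children_range[1], n_children_range[2])
      n_child <- if (length(sizes) == 1L) sizes else sample(sizes, 1L)
      remaining <- n_individuals - total
      fid <- sprintf("F%03d", fam)
      father <- sprintf("%s_01", fid)
      mother <- sprintf("%s_02", fid)
      take <- min(2L + n_child, remaining)
      members <- tibble::tibble(
        family_id = fid,
        individual_id = c(father, mother,
                          sprintf("%s_%02d", fid, 2L + seq_len(n_child)))[seq_len(take)],
        father_id = c(NA_character_, NA_character_,
                      rep(father, n_child))[seq_len(take)],
        mother_id = c(NA_character_, NA_character_,
                      rep(mother, n_child))[seq_len(take)],
        sex = c("male", "female",
                sample(c("male", "female"), n_child, replace = TRUE))[seq_len(take)],
        age = round(c(
          stats::runif(2, age_range_parents[1], age_range_parents[2]),
          stats::runif(n_child, age_range_children[1], age_range_children[2])
        ))[seq_len(take)]
      )
      rows[[fam]] <- members
      total <- total + take
    }
    ped <- dplyr::bind_rows(rows)
    class(ped) <- c("gxm_pedigree", class(ped))
    ped
  })
}

validate_pedigree <- function(pedigree) {
  req <- c("family_id", "individual_id", "father_id", "mother_id", "sex", "age")
  missing <- setdiff(req, names(pedigree))
  if (length(missing)) {
    stop("Pedigree is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pedigree$individual_id)) {
    stop("Duplicate individual ids in pedigree.", call. = FALSE)
  }
  non_founder <- !is.na(pedigree$father_id) | !is.na(pedigree$mother_id)
  parents <- c(pedigree$father_id[non_founder], pedigree$mother_id[non_founder])
  if (anyNA(parents)) {
    stop("Individuals must have either both parents or neither.", call. = FALSE)
  }
  if (!all(parents %in% pedigree$individual_id)) {
    stop("Pedigree references parents that are not present.", call. = FALSE)
  }
  idx <- match(pedigree$father_id, pedigree$individual_id)
  same_fam <- pedigree$family_id[idx] == pedigree$family_id
  if (any(!same_fam, na.rm = TRUE)) {
    stop("Parents must belong to the same family as their offspring.",
         call. = FALSE)
  }
  invisible(pedigree)
}

# Topological order: parents always precede children. Errors on cycles.
pedigree_order <- function(pedigree) {
  n <- nrow(pedigree)
  id <- pedigree$individual_id
  fa <- match(pedigree$father_id, id)
  mo <- match(pedigree$mother_id, id)
  placed <- logical(n)
  out <- integer(0)
  parent_placed <- function(p) is.na(p) | placed[ifelse(is.na(p), 1L, p)]
  repeat {
    ready <- !placed & parent_placed(fa) & parent_placed(mo)
    if (!any(ready)) break
    out <- c(out, which(ready))
    placed[ready] <- TRUE
  }
  if (length(out) != n) {
    stop("Pedigree contains a cycle (an individual is its own ancestor).",
         call. = FALSE)
  }
  out
}

#' Kinship matrix from a pedigree
#'
#' Computes kinship coefficients (the probability that one allele drawn at
#' random from each of two individuals is identical by descent) by the
#' standard recursion over a parents-first ordering: founders are unrelated
#' and non-inbred, `phi(i,i) = 0.5 * (1 + phi(father, mother))`, and
#' `phi(i,j) = 0.5 * (phi(father_i, j) + phi(mother_i, j))` for j not a
#' descendant of i. Families are processed independently (cross-family
#' kinship is zero), so the cost is quadratic in family size, not sample
#' size. Twice this matrix is the expected additive genetic covariance
#' structure used by the polygenic model.
#'
#' @param pedigree A pedigree tibble as returned by [build_pedigrees()].
#' @return A symmetric numeric matrix with dimnames = individual ids.
#' @export
#' @examples
#' ped <- build_pedigrees(6, n_children_range = c(4, 4), seed = 1)
#' kinship_matrix(ped)
kinship_matrix <- function(pedigree) {
  validate_pedigree(pedigree)
  ids <- pedigree$individual_id
  n <- length(ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (fid in unique(pedigree$family_id)) {
    rows <- which(pedigree$family_id == fid)
    sub <- pedigree[rows, ]
    ord <- pedigree_order(sub)
    sub <- sub[ord, ]
    m <- nrow(sub)
    f <- match(sub$father_id, sub$individual_id)
    mo <- match(sub$mother_id, sub$individual_id)
    ph <- matrix(0, m, m)
    for (i in seq_len(m)) {
      if (is.na(f[i])) {
        ph[i, i] <- 0.5
      } else {
        ph[i, i] <- 0.5 * (1 + ph[f[i], mo[i]])
        if (i > 1L) {
          j <- seq_len(i - 1L)
          ph[i, j] <- 0.5 * (ph[f[i], j] + ph[mo[i], j])
          ph[j, i] <- ph[i, j]
        }
      }
    }
    gi <- rows[ord]
    phi[gi, gi] <- ph
  }
  phi
}
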