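#' Derive a reproducible sub-seed for a pipeline component
#'
#' A single study seed is expanded into independent per-component (and
#' per-replicate) substreams so that, e.g., regenerating phenotypes for
#' replicate 7 never perturbs the genotype stream. The derivation is a small
#' deterministic integer hash kept strictly below 2^31 - 1.
#'
#' @param seed Integer study seed.
#' @param component Character scalar naming the stream (e.g. "genotypes").
#' @param replicate Integer replicate index (0 for study-level streams).
#' @return A single integer usable with [set.seed()].
#' @export
#' @examples
#' sub_seed(1, "genotypes")
#' sub_seed(1, "phenotypes", replicate = 12)
sub_seed <- function(seed, component, replicate = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  m <- 2147483647
  h <- as.numeric(seed) %% m
  codes <- utf8ToInt(component)
  for (k in c(codes, 257L, as.integer(replicate) + 1L)) {
    # 31 and 69621 are classic Lehmer-style multipliers; all arithmetic stays
    # in doubles well below 2^53 so the hash is exact.
    h <- (h * 69621 + as.numeric(k) * 31 + 17) %% m
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
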