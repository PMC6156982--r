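#' Read and write the study's delimited file formats
#'
#' Plain-text interchange for every simulated object:
#' * pedigree: whitespace-delimited linkage-style pre-makeped file - columns
#'   family, individual, father, mother (0 for founders), sex (1 = male,
#'   2 = female) - plus an age column;
#' * dosage / methylation matrices: tab-delimited, header row of marker ids,
#'   first column `individual_id`;
#' * marker maps: tab-delimited id, chromosome, position, plus role/pairing
#'   metadata;
#' * phenotypes: tab-delimited individual, TG1-TG4, age, sex;
#' * results and power tables: tab-delimited as produced.
#' Every writer's output is read back losslessly by the matching reader.
#'
#' @param pedigree,path,genotypes,methylation,phenotypes,tbl Objects/paths.
#' @name gxm_io
NULL

#' @rdname gxm_io
#' @export
write_pedigree <- function(pedigree, path) {
  out <- data.frame(
    family = pedigree$family_id,
    individual = pedigree$individual_id,
    father = ifelse(is.na(pedigree$father_id), "0", pedigree$father_id),
    mother = ifelse(is.na(pedigree$mother_id), "0", pedigree$mother_id),
    sex = ifelse(pedigree$sex == "male", 1L, 2L),
    age = pedigree$age
  )
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname gxm_io
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE,
                           col.names = c("family", "individual", "father",
                                         "mother", "sex", "age"),
                           colClasses = c(rep("character", 4), "integer",
                                         "numeric"))
  ped <- tibble::tibble(
    family_id = raw$family,
    individual_id = raw$individual,
    father_id = ifelse(raw$father == "0", NA_character_, raw$father),
    mother_id = ifelse(raw$mother == "0", NA_character_, raw$mother),
    sex = ifelse(raw$sex == 1L, "male", "female"),
    age = raw$age
  )
  class(ped) <- c("gxm_pedigree", class(ped))
  ped
}

write_matrix_tsv <- function(mat, path) {
  df <- data.frame(individual_id = rownames(mat), mat, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$individual_id
  m
}

#' @rdname gxm_io
#' @export
write_dosages <- function(genotypes, path) {
  write_matrix_tsv(genotypes$dosages, path)
}

#' @rdname gxm_io
#' @export
read_dosages <- function(path) {
  m <- read_matrix_tsv(path)
  storage.mode(m) <- "integer"
  m
}

#' @rdname gxm_io
#' @export
write_snp_map <- function(genotypes, path) {
  readr::write_tsv(genotypes$map, path)
  invisible(path)
}

#' @rdname gxm_io
#' @export
read_snp_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(snp_id = "c", chromosome = "i",
                                          position = "i", maf = "d",
                                          role = "c"))
}

#' @rdname gxm_io
#' @export
write_methylation <- function(methylation, path) {
  base <- sub("\\.tsv$", "", path)
  write_matrix_tsv(methylation$beta_visit2, paste0(base, "_visit2.tsv"))
  write_matrix_tsv(methylation$beta_visit4, paste0(base, "_visit4.tsv"))
  readr::write_tsv(methylation$map, paste0(base, "_map.tsv"))
  invisible(path)
}

#' @rdname gxm_io
#' @export
read_methylation <- function(path) {
  base <- sub("\\.tsv$", "", path)
  structure(list(
    beta_visit2 = read_matrix_tsv(paste0(base, "_visit2.tsv")),
    beta_visit4 = read_matrix_tsv(paste0(base, "_visit4.tsv")),
    map = readr::read_tsv(paste0(base, "_map.tsv"), show_col_types = FALSE,
                          col_types = readr::cols(cpg_id = "c",
                                                  chromosome = "i",
                                                  position = "i",
                                                  mean_beta = "d",
                                                  concentration = "d",
                                                  paired_snp = "c"))
  ), class = "gxm_methylation")
}

#' @rdname gxm_io
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path)
  invisible(path)
}

#' @rdname gxm_io
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(individual_id = "c",
                                          family_id = "c", TG1 = "d",
                                          TG2 = "d", TG3 = "d", TG4 = "d",
                                          age = "d", sex = "c"))
}

#' @rdname gxm_io
#' @export
write_results <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname gxm_io
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
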