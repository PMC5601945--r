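#' Read or write the plain-text genotype dialect
#'
#' The text dialect is a trio of tab-separated files with header rows:
#'
#' * `<prefix>.geno.tsv` — one subject per row, first column `subject_id`,
#'   one column per SNP holding the counted-allele dosage (`0`/`1`/`2`)
#'   or `NA` for missing;
#' * `<prefix>.snps.tsv` — columns `snp_id`, `chrom`, `pos`, `a1`, `a2`;
#' * `<prefix>.pheno.tsv` — columns `subject_id`, `status`
#'   (`case`/`control`) and optionally `sex`.
#'
#' The counted allele is `a1`, as for the PLINK reader.
#'
#' @param prefix Path prefix for the three files.
#' @return `read_geno_text()` returns a [geno_cohort()];
#'   `write_geno_text()` returns `prefix` invisibly.
#' @export
read_geno_text <- function(prefix) {
  gpath <- paste0(prefix, ".geno.tsv")
  spath <- paste0(prefix, ".snps.tsv")
  ppath <- paste0(prefix, ".pheno.tsv")
  for (f in c(gpath, spath, ppath)) {
    if (!file.exists(f)) abort(paste0("file not found: ", f))
  }
  snps <- readr::read_tsv(spath, col_types = readr::cols(
    snp_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), a1 = readr::col_character(),
    a2 = readr::col_character()
  ), progress = FALSE)
  pheno <- readr::read_tsv(ppath, col_types = readr::cols(
    subject_id = readr::col_character(), status = readr::col_character(),
    .default = readr::col_integer()
  ), progress = FALSE)
  geno <- readr::read_tsv(gpath, col_types = readr::cols(
    subject_id = readr::col_character(), .default = readr::col_integer()
  ), progress = FALSE)
  if (!identical(names(geno)[-1], snps$snp_id)) {
    abort("genotype columns do not match the SNP table (order and names must agree)")
  }
  if (!identical(geno$subject_id, pheno$subject_id)) {
    abort("genotype rows do not match the phenotype table")
  }
  dosage <- as.matrix(geno[, -1, drop = FALSE])
  geno_cohort(dosage, snps, pheno)
}

#' @rdname read_geno_text
#' @param cohort A [geno_cohort()] to write.
#' @export
write_geno_text <- function(cohort, prefix) {
  geno <- as_tibble(cohort$dosage)
  geno <- dplyr::bind_cols(tibble(subject_id = cohort$subjects$subject_id), geno)
  readr::write_tsv(geno, paste0(prefix, ".geno.tsv"), progress = FALSE)
  readr::write_tsv(cohort$snps, paste0(prefix, ".snps.tsv"), progress = FALSE)
  readr::write_tsv(cohort$subjects, paste0(prefix, ".pheno.tsv"), progress = FALSE)
  invisible(prefix)
}
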