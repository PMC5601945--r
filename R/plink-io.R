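PLINK_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))  # bed v1.00, SNP-major

# 2-bit bed code -> dosage of a1 (the first bim allele):
# 00 hom a1 = 2, 01 missing = NA, 10 het = 1, 11 hom a2 = 0
BED_DECODE <- c(2L, NA_integer_, 1L, 0L)
BED_ENCODE <- c(`2` = 0L, `1` = 2L, `0` = 3L)  # NA -> 1

#' Read a PLINK binary fileset
#'
#' Reads a SNP-major `.bed`/`.bim`/`.fam` trio into a [geno_cohort()].
#' The counted allele is the first allele column of the `.bim` file, so a
#' dosage of 2 means homozygous for that allele.  Phenotypes use the
#' standard coding 1 = control, 2 = case; any other code is an error.
#' Non-autosomal or non-biallelic records are dropped with a warning.
#'
#' @param prefix Path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#'   Alternatively pass explicit paths via `bed`, `bim`, `fam`.
#' @param bed,bim,fam Explicit file paths (override `prefix`).
#' @return A [geno_cohort()].
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  if (!is.null(prefix)) {
    bed <- bed %||% paste0(prefix, ".bed")
    bim <- bim %||% paste0(prefix, ".bim")
    fam <- fam %||% paste0(prefix, ".fam")
  }
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) abort(paste0("file not found: ", f))
  }
  bim_df <- readr::read_tsv(
    bim, col_names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"),
    col_types = readr::cols(
      chrom = readr::col_character(), snp_id = readr::col_character(),
      cm = readr::col_double(), pos = readr::col_integer(),
      a1 = readr::col_character(), a2 = readr::col_character()
    ), progress = FALSE
  )
  fam_df <- readr::read_delim(
    fam, delim = " ", col_names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
    col_types = "ccccii", progress = FALSE
  )
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  if (!all(fam_df$pheno %in% c(1L, 2L))) {
    abort("fam phenotype codes must be 1 (control) or 2 (case)")
  }
  bpv <- ceiling(n / 4)  # bytes per variant
  raw <- readBin(bed, what = "raw", n = 3 + bpv * m)
  if (length(raw) < 3 || !identical(raw[1:3], PLINK_MAGIC)) {
    abort("not a SNP-major PLINK v1 bed file (bad magic bytes)")
  }
  if (length(raw) != 3 + bpv * m) {
    abort(sprintf("bed size mismatch: expected %d data bytes for %d subjects x %d SNPs, found %d",
                  bpv * m, n, m, length(raw) - 3))
  }
  body <- as.integer(raw[-(1:3)])
  # unpack 4 genotypes per byte, sample-fastest
  codes <- matrix(0L, nrow = 4 * bpv, ncol = m)
  for (k in 0:3) {
    codes[seq.int(k + 1L, by = 4L, length.out = bpv), ] <-
      bitwAnd(bitwShiftR(body, 2L * k), 3L)
  }
  dosage <- matrix(BED_DECODE[codes[seq_len(n), , drop = FALSE] + 1L],
                   nrow = n, ncol = m)
  snps <- tibble(snp_id = bim_df$snp_id, chrom = bim_df$chrom,
                 pos = bim_df$pos, a1 = bim_df$a1, a2 = bim_df$a2)
  keep <- snps$chrom %in% as.character(1:22) &
    nchar(snps$a1) == 1L & nchar(snps$a2) == 1L & snps$a1 != snps$a2 &
    snps$a1 %in% c("A", "C", "G", "T") & snps$a2 %in% c("A", "C", "G", "T")
  if (!all(keep)) {
    warn(sprintf("dropping %d non-autosomal or non-biallelic SNP record(s)",
                 sum(!keep)))
    snps <- snps[keep, , drop = FALSE]
    dosage <- dosage[, keep, drop = FALSE]
  }
  subjects <- tibble(
    subject_id = fam_df$iid,
    status = c("control", "case")[fam_df$pheno],
    sex = fam_df$sex
  )
  geno_cohort(dosage, snps, subjects)
}

#' Write a PLINK binary fileset
#'
#' Writes `<prefix>.bed` (SNP-major v1), `.bim` and `.fam`.  Dosages are
#' encoded with the cohort's counted allele as the first `.bim` allele, so
#' [read_plink()] round-trips exactly.
#'
#' @param cohort A [geno_cohort()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(cohort, prefix) {
  n <- nrow(cohort$dosage)
  m <- ncol(cohort$dosage)
  bim <- data.frame(
    chrom = cohort$snps$chrom, snp_id = cohort$snps$snp_id, cm = 0L,
    pos = cohort$snps$pos, a1 = cohort$snps$a1, a2 = cohort$snps$a2
  )
  readr::write_tsv(bim, paste0(prefix, ".bim"), col_names = FALSE,
                   progress = FALSE)
  sex <- if ("sex" %in% names(cohort$subjects)) cohort$subjects$sex else 0L
  fam <- data.frame(
    fid = cohort$subjects$subject_id, iid = cohort$subjects$subject_id,
    pat = 0L, mat = 0L, sex = sex,
    pheno = ifelse(cohort$subjects$status == "case", 2L, 1L)
  )
  readr::write_delim(fam, paste0(prefix, ".fam"), delim = " ",
                     col_names = FALSE, progress = FALSE)
  bpv <- ceiling(n / 4)
  d <- cohort$dosage
  codes <- matrix(1L, nrow = 4 * bpv, ncol = m)  # pad/missing code 01
  enc <- ifelse(is.na(d), 1L, BED_ENCODE[as.character(d)])
  codes[seq_len(n), ] <- enc
  i1 <- seq.int(1L, by = 4L, length.out = bpv)
  bytes <- codes[i1, , drop = FALSE] + 4L * codes[i1 + 1L, , drop = FALSE] +
    16L * codes[i1 + 2L, , drop = FALSE] + 64L * codes[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(PLINK_MAGIC, con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}
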