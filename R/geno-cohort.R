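#' Case-control genotype cohort
#'
#' A `geno_cohort` bundles the three pieces of a case-control SNP dataset:
#' a subjects-by-SNPs dosage matrix, a SNP table and a phenotype table.
#' Dosages count copies of each SNP's *counted allele* (`a1`, the first
#' allele column of the variant table) and are `0`, `1`, `2` or `NA` for a
#' missing genotype.  Only autosomal biallelic SNPs are representable.
#'
#' @param dosage Integer/numeric matrix, subjects in rows, SNPs in columns,
#'   entries in `{0, 1, 2, NA}`.  Row names (if any) are ignored.
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos` (1-based
#'   base pairs), `a1`, `a2`; one row per dosage column, in column order.
#' @param subjects Data frame with columns `subject_id` and `status`
#'   (`"case"`/`"control"`); one row per dosage row.  An optional `sex`
#'   column is carried along.
#'
#' @return An object of class `geno_cohort`: a list with elements
#'   `dosage`, `snps` (tibble) and `subjects` (tibble).
#' @export
#' @examples
#' g <- geno_cohort(
#'   dosage = matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'                   dimnames = list(NULL, c("rs1", "rs2"))),
#'   snps = data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
#'                     pos = c(100L, 2000L), a1 = c("A", "C"),
#'                     a2 = c("G", "T")),
#'   subjects = data.frame(subject_id = c("s1", "s2", "s3"),
#'                         status = c("case", "control", "control"))
#' )
#' g
geno_cohort <- function(dosage, snps, subjects) {
  snps <- as_tibble(snps)
  subjects <- as_tibble(subjects)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  need_snp <- c("snp_id", "chrom", "pos", "a1", "a2")
  if (!all(need_snp %in% names(snps))) {
    abort(paste0("`snps` must have columns: ", paste(need_snp, collapse = ", ")))
  }
  if (!all(c("subject_id", "status") %in% names(subjects))) {
    abort("`subjects` must have columns `subject_id` and `status`")
  }
  if (nrow(subjects) != nrow(dosage) || nrow(snps) != ncol(dosage)) {
    abort(sprintf(
      "dimension mismatch: dosage is %d x %d but %d subjects and %d SNPs given",
      nrow(dosage), ncol(dosage), nrow(subjects), nrow(snps)
    ))
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("dosage entries must be 0, 1, 2 or NA")
  }
  if (!all(subjects$status %in% c("case", "control"))) {
    abort("`status` must be \"case\" or \"control\"")
  }
  if (anyDuplicated(snps$snp_id)) abort("duplicated snp_id in `snps`")
  if (anyDuplicated(subjects$subject_id)) abort("duplicated subject_id")
  dimnames(dosage) <- list(subjects$subject_id, snps$snp_id)
  structure(list(dosage = dosage, snps = snps, subjects = subjects),
            class = "geno_cohort")
}

#' @export
print.geno_cohort <- function(x, ...) {
  ncase <- sum(x$subjects$status == "case")
  nctrl <- sum(x$subjects$status == "control")
  miss <- mean(is.na(x$dosage))
  cat(sprintf(
    "<geno_cohort> %d subjects (%d cases, %d controls) x %d SNPs; %.2f%% missing\n",
    nrow(x$dosage), ncase, nctrl, ncol(x$dosage), 100 * miss
  ))
  invisible(x)
}

#' @export
dim.geno_cohort <- function(x) dim(x$dosage)

#' Subset a cohort by subjects and/or SNPs
#'
#' @param cohort A [geno_cohort()].
#' @param subjects Subject ids, or a logical/integer index over rows.
#' @param snps SNP ids, or a logical/integer index over columns.
#' @return A `geno_cohort` restricted to the selection, order preserved as
#'   given.
#' @export
subset_cohort <- function(cohort, subjects = NULL, snps = NULL) {
  i <- seq_len(nrow(cohort$dosage))
  j <- seq_len(ncol(cohort$dosage))
  if (!is.null(subjects)) {
    i <- if (is.character(subjects)) {
      match(subjects, cohort$subjects$subject_id)
    } else i[subjects]
    if (anyNA(i)) abort("unknown subject_id in `subjects`")
  }
  if (!is.null(snps)) {
    j <- if (is.character(snps)) match(snps, cohort$snps$snp_id) else j[snps]
    if (anyNA(j)) abort("unknown snp_id in `snps`")
  }
  geno_cohort(cohort$dosage[i, j, drop = FALSE],
              cohort$snps[j, , drop = FALSE],
              cohort$subjects[i, , drop = FALSE])
}

# status as 0/1 with case = 1
status01 <- function(status) as.integer(status == "case")
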