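#' Quality-control configuration
#'
#' Thresholds for the three per-SNP quality filters: Hardy-Weinberg
#' departure, genotype missingness and minor-allele frequency.
#'
#' @param hwe_p_min SNPs with HWE p-value below this are removed
#'   (default 0.01).
#' @param max_missing_rate SNPs with a missing-genotype fraction above
#'   this are removed (default 0.05).
#' @param maf_min SNPs with minor-allele frequency below this are removed
#'   (default 0.01); rare alleles are prone to genotyping artefacts.
#' @param hwe_sample Sample on which HWE is tested: `"controls_only"`
#'   (default, standard case-control practice) or `"all"`.
#' @param maf_sample Sample on which MAF is computed: `"all"` (default)
#'   or `"controls"`.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(hwe_p_min = 0.01, max_missing_rate = 0.05,
                      maf_min = 0.01,
                      hwe_sample = c("controls_only", "all"),
                      maf_sample = c("all", "controls")) {
  stopifnot(hwe_p_min > 0, hwe_p_min < 1,
            max_missing_rate > 0, max_missing_rate < 1,
            maf_min > 0, maf_min < 1)
  structure(list(hwe_p_min = hwe_p_min, max_missing_rate = max_missing_rate,
                 maf_min = maf_min, hwe_sample = match.arg(hwe_sample),
                 maf_sample = match.arg(maf_sample)),
            class = "qc_config")
}

#' Apply per-SNP quality-control filters
#'
#' Removes SNPs that (i) depart from Hardy-Weinberg equilibrium at
#' `hwe_p_min`, (ii) have a missing-genotype fraction above
#' `max_missing_rate`, or (iii) have minor-allele frequency below
#' `maf_min`.  A SNP may fail several rules but is removed once; retained
#' SNPs keep their original order.
#'
#' @param cohort A [geno_cohort()].
#' @param config A [qc_config()].
#' @return A list of class `qc_result` with elements `cohort` (the
#'   filtered [geno_cohort()]), `report` (per-rule counts and SNP id
#'   lists; see [write_qc_report()]) and `snp_stats` (per-SNP tibble with
#'   `maf`, `missing_rate`, `hwe_p` and the qc flags).
#' @export
apply_qc <- function(cohort, config = qc_config()) {
  stopifnot(inherits(cohort, "geno_cohort"), inherits(config, "qc_config"))
  d <- cohort$dosage
  miss_rate <- colMeans(is.na(d))

  hwe_rows <- if (config$hwe_sample == "controls_only") {
    cohort$subjects$status == "control"
  } else rep(TRUE, nrow(d))
  if (!any(hwe_rows)) abort("no subjects available for the HWE sample")
  dh <- d[hwe_rows, , drop = FALSE]
  n_aa <- colSums(dh == 2L, na.rm = TRUE)
  n_ab <- colSums(dh == 1L, na.rm = TRUE)
  n_bb <- colSums(dh == 0L, na.rm = TRUE)
  ok <- (n_aa + n_ab + n_bb) > 0
  hwe_p <- rep(1, ncol(d))
  if (any(ok)) {
    hwe_p[ok] <- hwe_test(n_aa[ok], n_ab[ok], n_bb[ok])$p_value
  }

  maf_rows <- if (config$maf_sample == "controls") {
    cohort$subjects$status == "control"
  } else rep(TRUE, nrow(d))
  f1 <- colMeans(d[maf_rows, , drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(f1, 1 - f1)
  maf[is.nan(maf)] <- 0  # all missing in the MAF sample

  hwe_fail <- hwe_p < config$hwe_p_min
  missing_fail <- miss_rate > config$max_missing_rate
  maf_fail <- maf < config$maf_min
  removed <- hwe_fail | missing_fail | maf_fail
  if (all(removed)) abort("no SNPs survive QC")

  snp_stats <- tibble(
    snp_id = cohort$snps$snp_id, maf = unname(maf),
    missing_rate = unname(miss_rate), hwe_p = unname(hwe_p),
    hwe_fail = unname(hwe_fail), missing_fail = unname(missing_fail),
    maf_fail = unname(maf_fail), removed = unname(removed)
  )
  report <- list(
    n_input = ncol(d),
    n_removed = sum(removed),
    n_retained = sum(!removed),
    n_by_rule = list(hwe_fail = sum(hwe_fail),
                     missing_fail = sum(missing_fail),
                     maf_fail = sum(maf_fail)),
    snps_by_rule = list(hwe_fail = cohort$snps$snp_id[hwe_fail],
                        missing_fail = cohort$snps$snp_id[missing_fail],
                        maf_fail = cohort$snps$snp_id[maf_fail]),
    config = unclass(config)
  )
  structure(list(cohort = subset_cohort(cohort, snps = !removed),
                 report = report, snp_stats = snp_stats),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<qc_result> %d SNPs in, %d removed (hwe %d, missing %d, maf %d), %d retained\n",
    r$n_input, r$n_removed, r$n_by_rule$hwe_fail, r$n_by_rule$missing_fail,
    r$n_by_rule$maf_fail, r$n_retained
  ))
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param qc A `qc_result` from [apply_qc()] (or its `report` element).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  report <- if (inherits(qc, "qc_result")) qc$report else qc
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
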