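#' Assign per-SNP minor alleles from the control cohort
#'
#' For each SNP the minor allele is the allele whose frequency among the
#' chosen reference subjects (controls by default) is strictly below 0.5,
#' computed over non-missing genotypes only.  A SNP whose frequency is
#' exactly 0.5 (tie), that is monomorphic, or that has no non-missing
#' reference genotype is *non-informative* and carries no minor allele;
#' downstream burden and scoring operations exclude such SNPs.
#'
#' @param cohort A [geno_cohort()].
#' @param sample Which subjects define allele frequencies: `"controls"`
#'   (default) or `"all"` (e.g. for pooled-cohort analyses).
#' @return A tibble of class `ma_assignment` with columns `snp_id`,
#'   `minor_allele` (`NA` when non-informative), `maf` (reference
#'   frequency of the minor allele), `informative`, and `minor_is_a1`
#'   (orientation of the stored dosage).
#' @export
assign_minor_alleles <- function(cohort, sample = c("controls", "all")) {
  sample <- match.arg(sample)
  rows <- if (sample == "controls") {
    cohort$subjects$status == "control"
  } else rep(TRUE, nrow(cohort$dosage))
  if (!any(rows)) abort("no control subjects to assign minor alleles from")
  f1 <- colMeans(cohort$dosage[rows, , drop = FALSE], na.rm = TRUE) / 2
  no_obs <- is.nan(f1)
  f1[no_obs] <- NA_real_
  minor_is_a1 <- f1 < 0.5
  informative <- !no_obs & f1 != 0.5 & f1 != 0 & f1 != 1
  maf <- pmin(f1, 1 - f1)
  out <- tibble(
    snp_id = cohort$snps$snp_id,
    minor_allele = dplyr::case_when(
      !informative ~ NA_character_,
      minor_is_a1 ~ cohort$snps$a1,
      TRUE ~ cohort$snps$a2
    ),
    maf = unname(maf),
    informative = unname(informative),
    minor_is_a1 = unname(ifelse(informative, minor_is_a1, NA))
  )
  class(out) <- c("ma_assignment", class(out))
  out
}

#' Minor-allele dosage matrix
#'
#' Reorients the stored counted-allele dosages so that each column counts
#' copies of the assigned minor allele.  Non-informative SNPs are all-`NA`
#' columns.
#'
#' @param cohort A [geno_cohort()].
#' @param ma An [assign_minor_alleles()] result covering the cohort's SNPs.
#' @return An integer matrix, subjects x SNPs.
#' @export
minor_dosage <- function(cohort, ma) {
  idx <- match(cohort$snps$snp_id, ma$snp_id)
  if (anyNA(idx)) abort("minor-allele assignment does not cover all SNPs")
  flip <- !ma$minor_is_a1[idx]
  d <- cohort$dosage
  if (any(flip, na.rm = TRUE)) {
    j <- which(!is.na(flip) & flip)
    d[, j] <- 2L - d[, j, drop = FALSE]
  }
  d[, !ma$informative[idx]] <- NA_integer_
  d
}

#' Per-subject minor-allele content (MAC)
#'
#' MAC is each subject's fraction of carried alleles that are minor over
#' the usable SNP panel: the minor-allele count divided by twice the
#' number of informative SNPs with a non-missing genotype in that subject
#' (per-allele normalization, so MAC of a Hardy-Weinberg subject is close
#' to the panel's mean MAF).  `denominator = "snps"` instead divides the
#' raw count by the number of usable SNPs, giving values in \[0, 2\].
#'
#' @param cohort A [geno_cohort()].
#' @param ma An [assign_minor_alleles()] result.
#' @param denominator `"alleles"` (default) or `"snps"`.
#' @return A tibble with columns `subject_id`, `status`, `mac` (`NA` when
#'   a subject has no usable SNP) and `n_used`.
#' @export
#' @examples
#' # a subject heterozygous at every informative SNP has MAC 0.5
compute_mac <- function(cohort, ma, denominator = c("alleles", "snps")) {
  denominator <- match.arg(denominator)
  d <- minor_dosage(cohort, ma)
  n_used <- rowSums(!is.na(d))
  count <- rowSums(d, na.rm = TRUE)
  denom <- if (denominator == "alleles") 2 * n_used else n_used
  mac <- ifelse(n_used == 0, NA_real_, count / denom)
  if (any(n_used == 0)) {
    warn(sprintf("%d subject(s) with no usable SNP: MAC set to NA",
                 sum(n_used == 0)))
  }
  tibble(subject_id = cohort$subjects$subject_id,
         status = cohort$subjects$status,
         mac = unname(mac), n_used = unname(n_used))
}

#' Group-comparison tests for burden and score summaries
#'
#' `two_sample_z()` compares two group means with the two-sample z-test
#' (unbiased sample variances, two-tailed normal p-value) and reports the
#' group means with their standard errors.  `f_test_variance()` tests
#' homogeneity of variance with the variance-ratio F-test, the larger
#' sample variance in the numerator and a two-tailed p-value.
#' `chi2_two_proportions()` compares two sample proportions with the
#' 1-df Pearson chi-square on the implied 2x2 table, without continuity
#' correction.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @return A one-row tibble.  `two_sample_z()`: `statistic` (z), `p_value`,
#'   `mean_a`, `mean_b`, `sem_a`, `sem_b`, `n_a`, `n_b`, `degenerate`.
#'   `f_test_variance()`: `statistic` (F), `df1`, `df2`, `p_value`,
#'   `degenerate`.  `chi2_two_proportions()`: `statistic`, `p_value`,
#'   `prop_1`, `prop_2`, `degenerate`.
#' @export
#' @examples
#' two_sample_z(c(1, 2, 3), c(4, 5, 6))
two_sample_z <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 values")
  va <- var(a); vb <- var(b)
  ma <- mean(a); mb <- mean(b)
  se <- sqrt(va / length(a) + vb / length(b))
  degenerate <- se == 0
  if (degenerate) {
    z <- if (ma == mb) 0 else sign(ma - mb) * Inf
    p <- if (ma == mb) 1 else 0
    if (!is.finite(z)) {
      warn("zero variance in both groups with unequal means: infinite z")
    }
  } else {
    z <- (ma - mb) / se
    p <- 2 * pnorm(-abs(z))
  }
  tibble(statistic = z, p_value = p, mean_a = ma, mean_b = mb,
         sem_a = sqrt(va / length(a)), sem_b = sqrt(vb / length(b)),
         n_a = length(a), n_b = length(b), degenerate = degenerate)
}

#' @rdname two_sample_z
#' @export
f_test_variance <- function(values_a, values_b) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 values")
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) abort("at least one group must have nonzero variance")
  if (va >= vb) {
    num <- va; den <- vb; df1 <- length(a) - 1; df2 <- length(b) - 1
  } else {
    num <- vb; den <- va; df1 <- length(b) - 1; df2 <- length(a) - 1
  }
  degenerate <- den == 0
  if (degenerate) {
    warn("zero variance in one group: infinite F")
    f <- Inf; p <- 0
  } else {
    f <- num / den
    p <- min(1, 2 * pf(f, df1, df2, lower.tail = FALSE))
  }
  tibble(statistic = f, df1 = df1, df2 = df2, p_value = p,
         degenerate = degenerate)
}

#' @rdname two_sample_z
#' @param x1,n1,x2,n2 Successes and totals of the two samples.
#' @export
chi2_two_proportions <- function(x1, n1, x2, n2) {
  stopifnot(x1 >= 0, x2 >= 0, n1 > 0, n2 > 0, x1 <= n1, x2 <= n2)
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    warn("degenerate pooled proportion: chi-square not assessable")
    return(tibble(statistic = 0, p_value = 1, prop_1 = x1 / n1,
                  prop_2 = x2 / n2, degenerate = TRUE))
  }
  ht <- suppressWarnings(
    prop.test(c(x1, x2), c(n1, n2), correct = FALSE)
  )
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         prop_1 = x1 / n1, prop_2 = x2 / n2, degenerate = FALSE)
}
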