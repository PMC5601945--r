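resolve_score_subset <- function(cohort, ma, weights, snp_subset) {
  if (length(snp_subset) == 0) abort("empty SNP subset")
  jw <- match(snp_subset, weights$snp_id)
  if (anyNA(jw)) abort("`snp_subset` contains SNPs without trained weights")
  if (any(!weights$usable[jw])) {
    abort("`snp_subset` contains SNPs whose weights are flagged unusable")
  }
  jc <- match(snp_subset, cohort$snps$snp_id)
  if (anyNA(jc)) abort("`snp_subset` contains SNPs absent from the cohort")
  list(jc = jc, jw = jw)
}

score_tibble <- function(cohort, score, n_used, type) {
  if (any(n_used == 0)) {
    warn(sprintf("%d subject(s) missing at all subset SNPs: score 0 with n_snps_used 0",
                 sum(n_used == 0)))
  }
  out <- tibble(subject_id = cohort$subjects$subject_id,
                status = cohort$subjects$status,
                score = as.vector(score), n_snps_used = as.integer(n_used))
  attr(out, "score_type") <- type
  class(out) <- c("score_vector", class(out))
  out
}

#' Weighted genetic risk score (wGRS)
#'
#' Sums, over the selected SNPs, a genotype weight times the SNP's
#' trained logistic beta: weight 1 for homozygous minor, 0.5 for
#' heterozygous, 0 for homozygous major.  A missing genotype contributes
#' 0 and is excluded from the per-subject SNP count (`n_snps_used`, the
#' covariate carried into the Nagelkerke model).  `center` subtracts the
#' per-SNP training-mean weight before summing, giving scores centered
#' near zero on the training cohort; raw scores are the default.
#'
#' @param cohort A [geno_cohort()] of the subjects to score.
#' @param ma Minor-allele assignment used to orient dosages (from the
#'   training cohort when scoring a validation cohort).
#' @param weights A [fit_snp_weights()] table from the training cohort.
#' @param snp_subset SNP ids defining the model; must all carry usable
#'   weights.
#' @param center Logical; subtract training-mean genotype weights
#'   (requires a `train_mean_w` attribute on `weights`, set by
#'   [fit_snp_weights()] consumers that opt in).  Default `FALSE`.
#' @return A tibble of class `score_vector`: `subject_id`, `status`,
#'   `score`, `n_snps_used`.
#' @export
compute_wgrs <- function(cohort, ma, weights, snp_subset, center = FALSE) {
  idx <- resolve_score_subset(cohort, ma, weights, snp_subset)
  D <- minor_dosage(cohort, ma)[, idx$jc, drop = FALSE]
  W <- D / 2
  n_used <- rowSums(!is.na(W))
  W[is.na(W)] <- 0
  beta <- weights$beta[idx$jw]
  score <- W %*% beta
  if (center) {
    mw <- attr(weights, "train_mean_w")
    if (is.null(mw)) abort("`weights` carries no training-mean weights to center on")
    score <- score - sum(mw[idx$jw] * beta)
  }
  score_tibble(cohort, score, n_used, "wgrs")
}

#' Polygenic risk score (PRS)
#'
#' Sums, over the selected SNPs, the minor-allele dosage (0/1/2) times
#' log10 of the SNP's trained odds ratio.  Missing genotypes contribute 0
#' and decrement `n_snps_used`.
#'
#' @inheritParams compute_wgrs
#' @return A tibble of class `score_vector`, as for [compute_wgrs()].
#' @export
compute_prs <- function(cohort, ma, weights, snp_subset) {
  idx <- resolve_score_subset(cohort, ma, weights, snp_subset)
  D <- minor_dosage(cohort, ma)[, idx$jc, drop = FALSE]
  storage.mode(D) <- "double"
  n_used <- rowSums(!is.na(D))
  D[is.na(D)] <- 0
  score <- D %*% log10(weights$odds_ratio[idx$jw])
  score_tibble(cohort, score, n_used, "prs")
}

#' Read/write a per-subject score table
#'
#' Tab-separated `(subject_id, status, score, n_snps_used)`;
#' round-trips exactly.
#'
#' @param scores A `score_vector` tibble.
#' @param path File path.
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(scores, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(), status = readr::col_character(),
    score = readr::col_double(), n_snps_used = readr::col_integer()
  ), progress = FALSE)
  class(out) <- c("score_vector", class(out))
  out
}
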