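eval_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("numeric labels must be 0/1")
    y <- as.integer(labels)
  } else {
    labels <- as.character(labels)
    if (!all(labels %in% c("case", "control"))) {
      abort("labels must be \"case\"/\"control\" or 0/1")
    }
    y <- status01(labels)
  }
  if (sum(y) < 1 || sum(1 - y) < 1) abort("need at least one case and one control")
  y
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' Rank-based (Mann-Whitney) AUC with ties counted one half, together
#' with the DeLong 95% confidence interval from case/control placement
#' variances.  If every score is identical the AUC is 0.5 with a
#' degenerate zero-width interval, flagged.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels `"case"`/`"control"` (or 0/1) per score.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `auc`, `ci_lo`, `ci_hi`, `n_cases`,
#'   `n_controls`, `degenerate`.
#' @export
#' @examples
#' score_auc(c(3, 1, 2, 0), c("case", "case", "control", "control"))
score_auc <- function(scores, labels, conf_level = 0.95) {
  y <- eval_labels(labels)
  ok <- !is.na(scores)
  scores <- scores[ok]
  y <- y[ok]
  n1 <- sum(y)
  n0 <- sum(1 - y)
  r_all <- rank(scores)
  cas <- y == 1
  # midrank placements (DeLong): V10 for cases, V01 for controls
  v10 <- (r_all[cas] - rank(scores[cas])) / n0
  v01 <- 1 - (r_all[!cas] - rank(scores[!cas])) / n1
  auc <- mean(v10)
  s10 <- if (n1 > 1) var(v10) else 0
  s01 <- if (n0 > 1) var(v01) else 0
  se <- sqrt(s10 / n1 + s01 / n0)
  degenerate <- se == 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble(auc = auc,
         ci_lo = max(0, auc - z * se), ci_hi = min(1, auc + z * se),
         n_cases = n1, n_controls = n0, degenerate = degenerate)
}

#' True-positive rate at 100% specificity
#'
#' The fraction of cases scoring *strictly above* the maximum control
#' score (so specificity is exactly 100%); a case tied with the best
#' control does not count.  The 95% confidence interval is Clopper-
#' Pearson on the case count.
#'
#' @inheritParams score_auc
#' @return A one-row tibble: `tpr`, `ci_lo`, `ci_hi`, `n_cases`,
#'   `n_controls`, `threshold`.
#' @export
tpr_full_specificity <- function(scores, labels, conf_level = 0.95) {
  y <- eval_labels(labels)
  ok <- !is.na(scores)
  scores <- scores[ok]
  y <- y[ok]
  thr <- max(scores[y == 0])
  x <- sum(scores[y == 1] > thr)
  n1 <- sum(y)
  ci <- binom.test(x, n1, conf.level = conf_level)$conf.int
  tibble(tpr = x / n1, ci_lo = ci[1], ci_hi = ci[2],
         n_cases = n1, n_controls = sum(1 - y), threshold = thr)
}

nagelkerke_r2_glm <- function(fit, ll0, n) {
  ll1 <- as.numeric(logLik(fit))
  (1 - exp((2 / n) * (ll0 - ll1))) / (1 - exp((2 / n) * ll0))
}

#' Nagelkerke variance explained by a score, over its covariate
#'
#' Difference in Nagelkerke pseudo-R-squared between the logistic model
#' `status ~ score + n_snps_used` and the covariate-only model
#' `status ~ n_snps_used`, where the covariate is the per-subject count
#' of SNPs actually used in the score.  Nagelkerke's R-squared rescales
#' the Cox-Snell measure by its attainable maximum:
#' \deqn{R^2_N = \frac{1 - \exp\{(2/n)(\ell_0 - \ell)\}}{1 - \exp\{(2/n)\ell_0\}}}
#' with \eqn{\ell_0} the intercept-only log-likelihood.  Values that are
#' negative by numerical noise (< 1e-12) are clipped to 0.
#'
#' @param score Per-subject score (wGRS or PRS).
#' @param n_snps_used Per-subject count of SNPs used in the score.
#' @param labels `"case"`/`"control"` (or 0/1).
#' @return A one-row tibble: `delta_r2`, `r2_full`, `r2_covariate`,
#'   `converged`.
#' @export
nagelkerke_delta_r2 <- function(score, n_snps_used, labels) {
  y <- eval_labels(labels)
  df <- data.frame(y = y, score = score, cov = as.numeric(n_snps_used))
  n <- nrow(df)
  fit0 <- glm(y ~ 1, family = binomial(), data = df)
  fit_cov <- glm(y ~ cov, family = binomial(), data = df)
  fit_full <- glm(y ~ score + cov, family = binomial(), data = df)
  conv <- fit_cov$converged && fit_full$converged
  if (!conv) {
    return(tibble(delta_r2 = NA_real_, r2_full = NA_real_,
                  r2_covariate = NA_real_, converged = FALSE))
  }
  ll0 <- as.numeric(logLik(fit0))
  r2f <- nagelkerke_r2_glm(fit_full, ll0, n)
  r2c <- nagelkerke_r2_glm(fit_cov, ll0, n)
  delta <- r2f - r2c
  if (delta < 0 && delta > -1e-12) delta <- 0
  tibble(delta_r2 = delta, r2_full = r2f, r2_covariate = r2c,
         converged = TRUE)
}

#' ROC coordinate table
#'
#' All distinct score thresholds with their sensitivity and specificity,
#' suitable for plotting or export.
#'
#' @inheritParams score_auc
#' @return A tibble: `threshold`, `sensitivity`, `specificity`.
#' @export
roc_points <- function(scores, labels) {
  y <- eval_labels(labels)
  thr <- c(-Inf, sort(unique(scores)))
  sens <- vapply(thr, function(t) mean(scores[y == 1] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[y == 0] <= t), numeric(1))
  tibble(threshold = thr, sensitivity = sens, specificity = spec)
}
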