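# Vectorized per-SNP univariate logistic regression.
#
# Fits case status ~ intercept + dosage independently for every SNP
# column by Newton/IRLS on the 2-parameter likelihood, all SNPs updated
# simultaneously through column reductions.  Missing dosages get weight
# zero.  Relative tolerance 1e-8, at most `max_iter` iterations.
snp_logit_irls <- function(D, y, max_iter = 50, tol = 1e-8) {
  n <- nrow(D)
  m <- ncol(D)
  storage.mode(D) <- "double"
  M <- !is.na(D)
  X <- D
  X[!M] <- 0
  Mn <- matrix(as.double(M), nrow = n)
  X2 <- X * X
  n_obs <- colSums(Mn)
  n_case <- as.vector(crossprod(y, Mn))
  # usable: both classes observed and dosage not constant among observed
  sx <- colSums(X)
  sxx <- colSums(X2)
  var_ok <- (n_obs * sxx - sx^2) > 0
  usable <- n_case > 0 & n_case < n_obs & var_ok
  p0 <- pmin(pmax(n_case / n_obs, 1e-12), 1 - 1e-12)
  a <- log(p0 / (1 - p0))
  b <- numeric(m)
  converged <- !usable  # nothing to do for unusable columns
  active <- usable
  iter <- 0L
  while (any(active) && iter < max_iter) {
    iter <- iter + 1L
    eta <- sweep(X, 2, b, "*")
    eta <- sweep(eta, 2, a, "+")
    mu <- plogis(eta)
    w <- mu * (1 - mu) * Mn
    r <- (y - mu) * Mn
    g1 <- colSums(r)
    g2 <- colSums(X * r)
    h11 <- colSums(w)
    h12 <- colSums(X * w)
    h22 <- colSums(X2 * w)
    det <- h11 * h22 - h12^2
    bad <- active & (!is.finite(det) | det <= 1e-300)
    if (any(bad)) {
      usable[bad] <- FALSE
      active[bad] <- FALSE
    }
    da <- ifelse(active, (h22 * g1 - h12 * g2) / det, 0)
    db <- ifelse(active, (h11 * g2 - h12 * g1) / det, 0)
    a <- a + da
    b <- b + db
    done <- active & (abs(da) < tol * (1 + abs(a))) &
      (abs(db) < tol * (1 + abs(b)))
    converged[done] <- TRUE
    active[done] <- FALSE
  }
  # quasi-separation: runaway slope
  sep <- usable & (abs(b) > 15 | !is.finite(b))
  usable <- usable & !sep & converged
  # Wald standard errors from the final information matrix
  eta <- sweep(X, 2, b, "*")
  eta <- sweep(eta, 2, a, "+")
  mu <- plogis(eta)
  w <- mu * (1 - mu) * Mn
  h11 <- colSums(w)
  h12 <- colSums(X * w)
  h22 <- colSums(X2 * w)
  det <- h11 * h22 - h12^2
  se <- ifelse(usable & det > 0, sqrt(h11 / det), NA_real_)
  pval <- ifelse(usable, 2 * pnorm(-abs(b / se)), NA_real_)
  # log-likelihood (observed entries only)
  ll <- colSums((y * eta - log1p(exp(eta))) * Mn)
  lapply(list(intercept = a, beta = ifelse(usable, b, NA_real_), se = se,
              p_value = pval, odds_ratio = ifelse(usable, exp(b), NA_real_),
              n = n_obs, usable = usable, converged = converged,
              loglik = ll),
         unname)
}

#' Per-SNP logistic association
#'
#' Maximum-likelihood logistic regression of case status on the
#' minor-allele dosage (0/1/2) of a single SNP, with intercept; Wald
#' standard error and p-value.  A fit with complete separation, constant
#' dosage, or non-convergence within 50 Newton iterations is flagged
#' unusable (such SNPs are excluded from risk models).
#'
#' @param dosage Numeric vector in `{0,1,2,NA}`.
#' @param status Character (`"case"`/`"control"`), factor, or 0/1 vector.
#' @return An object of class `snp_logit` with `tidy()` and `glance()`
#'   methods; elements `beta`, `se`, `p_value`, `odds_ratio`,
#'   `intercept`, `n`, `usable`, `converged`, `loglik`.
#' @export
#' @examples
#' d <- rep(c(1, 0), c(30, 30))
#' y <- rep(c("case", "control", "case", "control"), c(20, 10, 10, 20))
#' fit_snp_logistic(d, y)$odds_ratio  # the 2x2 odds ratio, 4
fit_snp_logistic <- function(dosage, status) {
  y <- if (is.numeric(status)) as.numeric(status) else
    as.numeric(status01(as.character(status)))
  ok <- !is.na(dosage) & !is.na(y)
  if (sum(y[ok] == 1) < 1 || sum(y[ok] == 0) < 1) {
    abort("need at least one case and one control with non-missing dosage")
  }
  fit <- snp_logit_irls(matrix(as.numeric(dosage), ncol = 1), y)
  structure(lapply(fit, function(x) x[[1]]), class = "snp_logit")
}

#' @export
print.snp_logit <- function(x, ...) {
  cat(sprintf(
    "<snp_logit> beta %.4f (se %.4f), OR %.4f, p %.3g, n %d%s\n",
    x$beta, x$se, x$odds_ratio, x$p_value, x$n,
    if (!x$usable) " [unusable]" else ""
  ))
  invisible(x)
}

#' @export
tidy.snp_logit <- function(x, ...) {
  tibble(term = c("(Intercept)", "dosage"),
         estimate = c(x$intercept, x$beta),
         std.error = c(NA_real_, x$se),
         statistic = c(NA_real_, x$beta / x$se),
         p.value = c(NA_real_, x$p_value))
}

#' @export
glance.snp_logit <- function(x, ...) {
  tibble(logLik = x$loglik, nobs = x$n, converged = x$converged,
         usable = x$usable, odds_ratio = x$odds_ratio)
}

#' Fit per-SNP logistic weights on a training cohort
#'
#' Runs the univariate logistic association of [fit_snp_logistic()] for
#' every informative SNP at once (dosages oriented to the minor allele),
#' yielding the weight table used by [compute_wgrs()] and
#' [compute_prs()].  Non-informative, constant, separated or
#' non-convergent SNPs are flagged unusable and excluded from models.
#'
#' @param cohort A [geno_cohort()] (the *training* cohort).
#' @param ma An [assign_minor_alleles()] result from the same cohort.
#' @return A tibble of class `snp_weights`: `snp_id`, `minor_allele`,
#'   `maf`, `beta`, `se`, `p_value`, `odds_ratio`, `n`, `usable`.
#' @export
fit_snp_weights <- function(cohort, ma) {
  D <- minor_dosage(cohort, ma)
  y <- as.numeric(status01(cohort$subjects$status))
  if (sum(y) < 1 || sum(1 - y) < 1) {
    abort("training cohort needs at least one case and one control")
  }
  fit <- snp_logit_irls(D, y)
  out <- tibble(
    snp_id = cohort$snps$snp_id,
    minor_allele = ma$minor_allele[match(cohort$snps$snp_id, ma$snp_id)],
    maf = ma$maf[match(cohort$snps$snp_id, ma$snp_id)],
    beta = fit$beta, se = fit$se, p_value = fit$p_value,
    odds_ratio = fit$odds_ratio, n = as.integer(fit$n),
    usable = fit$usable
  )
  # per-SNP training mean of the {0, 0.5, 1} genotype weight (missing -> 0),
  # for the optional centered wGRS variant
  W <- D / 2
  W[is.na(W)] <- 0
  attr(out, "train_mean_w") <- colMeans(W)
  class(out) <- c("snp_weights", class(out))
  out
}

#' Read/write a SNP-weight table
#'
#' Tab-separated serialization of [fit_snp_weights()] output;
#' round-trips exactly.
#'
#' @param weights A `snp_weights` tibble.
#' @param path File path.
#' @return `write_snp_weights()` returns `path` invisibly;
#'   `read_snp_weights()` returns the tibble.
#' @export
write_snp_weights <- function(weights, path) {
  readr::write_tsv(weights, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_snp_weights
#' @export
read_snp_weights <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(), minor_allele = readr::col_character(),
    maf = readr::col_double(), beta = readr::col_double(),
    se = readr::col_double(), p_value = readr::col_double(),
    odds_ratio = readr::col_double(), n = readr::col_integer(),
    usable = readr::col_logical()
  ), progress = FALSE)
  class(out) <- c("snp_weights", class(out))
  out
}
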