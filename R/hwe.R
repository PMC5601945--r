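#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Tests departure from Hardy-Weinberg proportions at a biallelic SNP.
#' The default is the 1-df Pearson goodness-of-fit chi-square against the
#' expected counts \eqn{(n p^2, 2 n p q, n q^2)} with the allele frequency
#' estimated from the sample; `method = "exact"` gives the standard exact
#' enumeration test over heterozygote counts conditional on the allele
#' counts.  A monomorphic SNP has no assessable departure and returns
#' p = 1 with the `monomorphic` flag set.
#'
#' All three count arguments are vectorized.
#'
#' @param n_hom_a1,n_het,n_hom_a2 Non-negative integer genotype counts
#'   (homozygous first allele, heterozygous, homozygous second allele).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return A tibble with columns `statistic` (chi-square statistic, `NA`
#'   for the exact test), `p_value` and `monomorphic`.
#' @export
#' @examples
#' hwe_test(25, 50, 25)   # observed equals expected: p = 1
#' hwe_test(50, 0, 50)    # total heterozygote deficit
hwe_test <- function(n_hom_a1, n_het, n_hom_a2, method = c("chisq", "exact")) {
  method <- match.arg(method)
  k <- max(length(n_hom_a1), length(n_het), length(n_hom_a2))
  o_aa <- rep_len(as.numeric(n_hom_a1), k)
  o_ab <- rep_len(as.numeric(n_het), k)
  o_bb <- rep_len(as.numeric(n_hom_a2), k)
  if (any(o_aa < 0 | o_ab < 0 | o_bb < 0, na.rm = TRUE)) {
    abort("genotype counts must be non-negative")
  }
  n <- o_aa + o_ab + o_bb
  if (any(n <= 0)) abort("total genotype count must be positive")
  p <- (2 * o_aa + o_ab) / (2 * n)
  mono <- p == 0 | p == 1
  if (method == "chisq") {
    q <- 1 - p
    e_aa <- n * p^2
    e_ab <- 2 * n * p * q
    e_bb <- n * q^2
    stat <- ifelse(mono, 0,
                   (o_aa - e_aa)^2 / e_aa + (o_ab - e_ab)^2 / e_ab +
                     (o_bb - e_bb)^2 / e_bb)
    pval <- ifelse(mono, 1, pchisq(stat, df = 1, lower.tail = FALSE))
  } else {
    stat <- rep(NA_real_, k)
    pval <- vapply(seq_len(k), function(i) {
      if (mono[i]) return(1)
      hwe_exact_p(o_aa[i], o_ab[i], o_bb[i])
    }, numeric(1))
  }
  tibble(statistic = stat, p_value = pval, monomorphic = mono)
}

# Exact SNP-HWE: sum of probabilities of heterozygote counts no more
# likely than the observed one, conditional on allele counts.
hwe_exact_p <- function(o_aa, o_ab, o_bb) {
  n <- o_aa + o_ab + o_bb
  n_a <- 2 * o_aa + o_ab          # rarer-allele count below
  if (n_a > n) n_a <- 2 * n - n_a
  hets <- seq.int(n_a %% 2, n_a, by = 2)
  logp <- vapply(hets, function(h) {
    haa <- (n_a - h) / 2
    hbb <- n - haa - h
    lgamma(n + 1) - lgamma(haa + 1) - lgamma(h + 1) - lgamma(hbb + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(n_a + 1) - lgamma(2 * n - n_a + 1))
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  min(1, sum(prob[prob <= prob[match(o_ab, hets)] * (1 + 1e-12)]))
}
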