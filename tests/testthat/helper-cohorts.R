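# fixture builders -----------------------------------------------------

# cohort from an explicit dosage matrix; SNPs 10 kb apart on chromosome 1
# unless positions given
make_cohort <- function(dosage, statuses, pos = NULL, chrom = NULL,
                        a1 = NULL, a2 = NULL) {
  m <- ncol(dosage)
  geno_cohort(
    dosage,
    snps = tibble::tibble(
      snp_id = sprintf("rs%03d", seq_len(m)),
      chrom = chrom %||% rep("1", m),
      pos = as.integer(pos %||% seq(10000, by = 10000, length.out = m)),
      a1 = a1 %||% rep("A", m), a2 = a2 %||% rep("G", m)
    ),
    subjects = tibble::tibble(
      subject_id = sprintf("s%03d", seq_len(nrow(dosage))),
      status = statuses
    )
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random cohort with known per-SNP allele frequencies, HWE genotypes
random_cohort <- function(n_case, n_ctrl, m, miss = 0, seed = 1) {
  set.seed(seed)
  f <- runif(m, 0.05, 0.5)
  n <- n_case + n_ctrl
  d <- sapply(f, function(p) rbinom(n, 2, p))
  if (miss > 0) d[runif(length(d)) < miss] <- NA_integer_
  make_cohort(d, rep(c("case", "control"), c(n_case, n_ctrl)))
}

small_sim <- function(seed, n = 60, m = 200, ...) {
  args <- list(n_cases = n, n_controls = n, m_snps = m, seed = seed, ...)
  if (is.null(args$n_chrom)) args$n_chrom <- 2
  simulate_cohorts(do.call(sim_config, args))
}

# all-pairs AUC oracle (concordant pairs, ties half)
brute_auc <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}
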