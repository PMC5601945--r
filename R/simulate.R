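#' Simulation configuration for paired case-control cohorts
#'
#' Parameters of the generative model used by [simulate_cohorts()]:
#' independent cohorts of autosomal biallelic SNPs with a uniform MAF
#' spectrum, blockwise AR(1) latent-Gaussian linkage disequilibrium,
#' small polygenic liability effects with a tunable minor-allele risk
#' orientation, liability-threshold case status and MCAR missingness.
#'
#' @param n_cases,n_controls Subjects per cohort (defaults 500 + 500).
#' @param n_cohorts Number of independent cohorts sharing one SNP table
#'   and one set of true effects (default 2: training + validation).
#' @param m_snps Number of SNPs (default 5000).
#' @param maf_range Range of the uniform target-MAF distribution
#'   (default `c(0.01, 0.5)`).
#' @param ld_block_size SNPs per LD block (default 10; blocks truncate
#'   at chromosome ends).
#' @param ld_rho Within-block latent AR(1) correlation in `[0, 1)`
#'   (default 0.9).  Dichotomizing the latent attenuates genotype
#'   correlation, so realized adjacent-pair r-squared is well below
#'   `ld_rho^2` (about 0.5 at rho 0.9 for common alleles).
#' @param causal_fraction Fraction of SNPs with a liability effect
#'   (default 0.05).
#' @param effect_sd Liability-scale per-allele effect standard deviation
#'   (effect magnitudes are |N(0, effect_sd^2)|; default 0.15).
#' @param minor_risk_prob Probability that a causal SNP's risk allele is
#'   its (population-)minor allele; values above 0.5 create the
#'   minor-allele enrichment phenomenon (default 0.7).
#' @param prevalence Population case prevalence defining the liability
#'   threshold (default 0.01, a common lifetime-risk figure for the
#'   target phenotype class).
#' @param missing_rate Missing-completely-at-random genotype rate
#'   (default 0.01).
#' @param n_chrom Number of chromosomes the SNPs are spread over
#'   (default 5).
#' @param spacing_bp Mean inter-marker spacing in base pairs (default
#'   4000, array-scale density: a 200 kb window spans ~50 markers).
#' @param maf_jitter Half-width of a per-cohort uniform MAF perturbation
#'   (default 0; use > 0 to stress-test cross-cohort harmonization).
#' @param model `"liability"` (default) or `"logistic"` case-status
#'   model.
#' @param seed Integer seed; every draw in [simulate_cohorts()] is
#'   reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 500, n_controls = 500, n_cohorts = 2,
                       m_snps = 5000, maf_range = c(0.01, 0.5),
                       ld_block_size = 10, ld_rho = 0.9,
                       causal_fraction = 0.05, effect_sd = 0.15,
                       minor_risk_prob = 0.7, prevalence = 0.01,
                       missing_rate = 0.01, n_chrom = 5,
                       spacing_bp = 4000, maf_jitter = 0,
                       model = c("liability", "logistic"), seed = NULL) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_cohorts >= 1, m_snps >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
            causal_fraction >= 0, causal_fraction <= 1, effect_sd >= 0,
            minor_risk_prob >= 0, minor_risk_prob <= 1,
            prevalence > 0, prevalence < 1,
            missing_rate >= 0, missing_rate < 0.5, maf_jitter >= 0)
  structure(list(
    n_cases = n_cases, n_controls = n_controls, n_cohorts = n_cohorts,
    m_snps = m_snps, maf_range = maf_range, ld_block_size = ld_block_size,
    ld_rho = ld_rho, causal_fraction = causal_fraction,
    effect_sd = effect_sd, minor_risk_prob = minor_risk_prob,
    prevalence = prevalence, missing_rate = missing_rate,
    n_chrom = n_chrom, spacing_bp = spacing_bp, maf_jitter = maf_jitter,
    model = match.arg(model), seed = seed
  ), class = "sim_config")
}

# chromosome and LD-block membership shared by the simulator and
# empirical_ld_check(); blocks are contiguous runs restarting at each
# chromosome
sim_block_ids <- function(m_snps, n_chrom, ld_block_size) {
  per <- rep(m_snps %/% n_chrom, n_chrom) +
    c(rep(1, m_snps %% n_chrom), rep(0, n_chrom - m_snps %% n_chrom))
  chrom <- rep.int(seq_len(n_chrom), per)
  within <- unlist(lapply(per, seq_len), use.names = FALSE)
  block <- cumsum(c(TRUE, diff(chrom) != 0 |
                      (within[-1] - 1) %% ld_block_size == 0))
  list(chrom = chrom, block = block)
}

ar1_sigma <- function(b, rho) rho^abs(outer(seq_len(b), seq_len(b), "-"))

# draw latent haplotype values for all SNPs of the accepted subjects:
# blocks with causal SNPs are filled from the exact AR(1) Gaussian
# conditional given the already-drawn causal latents, other blocks are
# drawn unconditionally
fill_block_latents <- function(n, blocks, causal_in_block, z_causal, rho) {
  m <- length(blocks$block)
  Z <- matrix(NA_real_, n, m)
  chol_cache <- list()
  for (b in unique(blocks$block)) {
    idx <- which(blocks$block == b)
    bs <- length(idx)
    O <- which(idx %in% causal_in_block)
    if (!length(O)) {
      key <- as.character(bs)
      if (is.null(chol_cache[[key]])) {
        chol_cache[[key]] <- chol(ar1_sigma(bs, rho))
      }
      Z[, idx] <- matrix(rnorm(n * bs), n) %*% chol_cache[[key]]
    } else {
      zo <- z_causal[, match(idx[O], causal_in_block), drop = FALSE]
      U <- setdiff(seq_len(bs), O)
      if (length(U)) {
        S <- ar1_sigma(bs, rho)
        A <- S[U, O, drop = FALSE] %*% solve(S[O, O, drop = FALSE])
        cc <- S[U, U, drop = FALSE] - A %*% S[O, U, drop = FALSE]
        cc <- (cc + t(cc)) / 2
        L <- chol(cc + diag(1e-12, length(U)))
        Z[, idx[U]] <- zo %*% t(A) + matrix(rnorm(n * length(U)), n) %*% L
      }
      Z[, idx[O]] <- zo
    }
  }
  Z
}

# draw latents for the causal SNPs only (joint within block), for cheap
# liability screening of candidate subjects
draw_causal_latents <- function(n, blocks, causal_idx, rho) {
  if (!length(causal_idx)) return(matrix(0, n, 0))
  Z <- matrix(NA_real_, n, length(causal_idx))
  for (b in unique(blocks$block[causal_idx])) {
    sel <- which(blocks$block[causal_idx] == b)
    off <- causal_idx[sel] - min(which(blocks$block == b)) + 1
    S <- ar1_sigma(max(off), rho)[off, off, drop = FALSE]
    Z[, sel] <- matrix(rnorm(n * length(sel)), n) %*% chol(S)
  }
  Z
}

#' Simulate paired case-control cohorts with known ground truth
#'
#' Haplotypes are drawn from a blockwise AR(1) latent Gaussian; a
#' haplotype carries a SNP's `a1` allele when its latent value exceeds
#' the quantile matching that SNP's target frequency, so Hardy-Weinberg
#' proportions hold marginally and within-block LD decays with marker
#' distance.  Liability is the sum of causal risk-allele dosages times
#' their effects plus standard-normal noise; a subject is a case when
#' liability exceeds the threshold implied by `prevalence`.  Cases and
#' controls are accumulated to the target counts by rejection sampling
#' (made tractable by screening candidates on their causal-SNP latents
#' and filling the remaining latents from the exact AR(1) conditional —
#' distributionally identical to full rejection).  Genotypes are then
#' masked MCAR at `missing_rate`.  All cohorts share the SNP table and
#' the true effects; everything is reproducible from `seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_result`: `cohorts` (list of
#'   [geno_cohort()]s), `truth` (list with the per-SNP tibble `snps` —
#'   `causal`, `effect`, `risk_allele`, `target_maf` — and the
#'   per-subject tibble `subjects` with liabilities), and `config`.
#' @export
simulate_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- config$m_snps
  layout <- sim_block_ids(m, config$n_chrom, config$ld_block_size)
  pos <- unlist(lapply(split(seq_len(m), layout$chrom), function(idx) {
    cumsum(pmax(1L, round(rexp(length(idx), 1 / config$spacing_bp))))
  }), use.names = FALSE)
  alleles <- t(replicate(m, sample(c("A", "C", "G", "T"), 2)))
  snps <- tibble(
    snp_id = sprintf("snp%05d", seq_len(m)),
    chrom = as.character(layout$chrom), pos = as.integer(pos),
    a1 = alleles[, 1], a2 = alleles[, 2]
  )
  f <- runif(m, config$maf_range[1], config$maf_range[2])  # freq of a1
  causal <- runif(m) < config$causal_fraction
  effect <- ifelse(causal, abs(rnorm(m, 0, config$effect_sd)), 0)
  risk_is_minor <- causal & (runif(m) < config$minor_risk_prob)
  risk_allele <- ifelse(!causal, NA_character_,
                        ifelse(risk_is_minor, snps$a1, snps$a2))
  cidx <- which(causal)
  f_risk <- ifelse(risk_is_minor, f, 1 - f)[cidx]
  beta_c <- effect[cidx]
  mean_g <- sum(2 * f_risk * beta_c)
  var_g <- sum(2 * f_risk * (1 - f_risk) * beta_c^2)
  thr_liab <- mean_g + qnorm(1 - config$prevalence) * sqrt(var_g + 1)
  cohorts <- vector("list", config$n_cohorts)
  subj_truth <- vector("list", config$n_cohorts)
  for (co in seq_len(config$n_cohorts)) {
    fc <- f
    if (config$maf_jitter > 0) {
      fc <- pmin(pmax(f + runif(m, -config$maf_jitter, config$maf_jitter),
                      0.005), 0.995)
    }
    zcut <- qnorm(1 - fc)
    sim <- sim_one_cohort(config, layout, cidx, beta_c, risk_is_minor[cidx],
                          zcut, thr_liab, mean_g)
    d <- sim$dosage
    if (config$missing_rate > 0) {
      d[runif(length(d)) < config$missing_rate] <- NA_integer_
    }
    num <- stats::ave(seq_along(sim$status), sim$status, FUN = seq_along)
    ids <- sprintf("c%d_%s%04d", co,
                   ifelse(sim$status == "case", "case", "ctrl"), num)
    subjects <- tibble(subject_id = ids, status = sim$status)
    cohorts[[co]] <- geno_cohort(d, snps, subjects)
    subj_truth[[co]] <- tibble(cohort = co, subject_id = ids,
                               liability = sim$liability,
                               genetic_liability = sim$genetic)
  }
  truth <- list(
    snps = dplyr::bind_cols(snps, tibble(target_maf = f, causal = causal,
                                         effect = effect,
                                         risk_allele = risk_allele)),
    subjects = dplyr::bind_rows(subj_truth),
    liability_threshold = thr_liab
  )
  structure(list(cohorts = cohorts, truth = truth, config = config),
            class = "sim_result")
}

# rejection-sample one cohort to its case/control quotas
sim_one_cohort <- function(config, layout, cidx, beta_c, risk_minor_c,
                           zcut, thr_liab, mean_g) {
  n_cases <- config$n_cases
  n_controls <- config$n_controls
  m <- config$m_snps
  acc_z1 <- list(); acc_z2 <- list()
  acc_g <- list(); acc_l <- list(); acc_s <- list()
  got_case <- 0; got_ctrl <- 0
  drawn <- 0
  max_draws <- ceiling(20 * (n_cases / config$prevalence +
                               n_controls / (1 - config$prevalence))) + 1e4
  while (got_case < n_cases || got_ctrl < n_controls) {
    need_case <- n_cases - got_case
    need_ctrl <- n_controls - got_ctrl
    B <- min(50000, max(2000, ceiling(
      1.3 * max(need_case / config$prevalence,
                need_ctrl / (1 - config$prevalence)))))
    drawn <- drawn + B
    if (drawn > max_draws) {
      abort("could not reach the requested case/control counts; prevalence too extreme for the draw budget")
    }
    z1 <- draw_causal_latents(B, layout, cidx, config$ld_rho)
    z2 <- draw_causal_latents(B, layout, cidx, config$ld_rho)
    if (length(cidx)) {
      d_risk <- sweep(z1, 2, zcut[cidx], ">") + sweep(z2, 2, zcut[cidx], ">")
      flip <- !risk_minor_c
      if (any(flip)) d_risk[, flip] <- 2 - d_risk[, flip, drop = FALSE]
      g <- as.vector(d_risk %*% beta_c)
    } else {
      g <- numeric(B)
    }
    if (config$model == "liability") {
      liab <- g + rnorm(B)
      is_case <- liab > thr_liab
    } else {
      alpha <- log(config$prevalence / (1 - config$prevalence)) - mean_g
      p_case <- plogis(alpha + g)
      is_case <- runif(B) < p_case
      liab <- g
    }
    take_case <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
    take_ctrl <- which(!is_case)[seq_len(min(need_ctrl, sum(!is_case)))]
    take <- c(take_case, take_ctrl)
    if (length(take)) {
      acc_z1[[length(acc_z1) + 1]] <- z1[take, , drop = FALSE]
      acc_z2[[length(acc_z2) + 1]] <- z2[take, , drop = FALSE]
      acc_g[[length(acc_g) + 1]] <- g[take]
      acc_l[[length(acc_l) + 1]] <- liab[take]
      acc_s[[length(acc_s) + 1]] <- rep(c("case", "control"),
                                        c(length(take_case), length(take_ctrl)))
    }
    got_case <- got_case + length(take_case)
    got_ctrl <- got_ctrl + length(take_ctrl)
  }
  status <- unlist(acc_s)
  o <- order(factor(status, levels = c("case", "control")))
  n <- length(status)
  z1c <- do.call(rbind, acc_z1)[o, , drop = FALSE]
  z2c <- do.call(rbind, acc_z2)[o, , drop = FALSE]
  Z1 <- fill_block_latents(n, layout, cidx, z1c, config$ld_rho)
  Z2 <- fill_block_latents(n, layout, cidx, z2c, config$ld_rho)
  dosage <- sweep(Z1, 2, zcut, ">") + sweep(Z2, 2, zcut, ">")
  storage.mode(dosage) <- "integer"
  list(dosage = dosage, status = status[o],
       liability = unlist(acc_l)[o], genetic = unlist(acc_g)[o])
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d cohort(s), %d SNPs, %d causal; model: %s\n",
              length(x$cohorts), nrow(x$truth$snps),
              sum(x$truth$snps$causal), x$config$model))
  invisible(x)
}

#' Empirical LD diagnostics of a simulated cohort
#'
#' Summarizes realized linkage disequilibrium against the generative
#' block structure: mean r-squared of adjacent within-block pairs, of
#' adjacent cross-block pairs, and of all within-block pairs.
#'
#' @param cohort A [geno_cohort()] from [simulate_cohorts()].
#' @param config The [sim_config()] that generated it.
#' @return A one-row tibble: `mean_adjacent_within_r2`,
#'   `mean_within_block_r2`, `mean_adjacent_cross_r2`, `n_within_pairs`,
#'   `n_cross_pairs`.
#' @export
empirical_ld_check <- function(cohort, config) {
  m <- ncol(cohort$dosage)
  layout <- sim_block_ids(m, config$n_chrom, config$ld_block_size)
  adj_same <- which(diff(layout$block) == 0)
  adj_cross <- which(diff(layout$block) != 0 &
                       diff(layout$chrom) == 0)
  r2_adj_within <- vapply(adj_same, function(i) {
    pairwise_r2(cohort$dosage[, i], cohort$dosage[, i + 1])
  }, numeric(1))
  r2_adj_cross <- vapply(adj_cross, function(i) {
    pairwise_r2(cohort$dosage[, i], cohort$dosage[, i + 1])
  }, numeric(1))
  within <- purrr::map(unique(layout$block), function(b) {
    idx <- which(layout$block == b)
    if (length(idx) < 2) return(numeric())
    pr <- utils::combn(idx, 2)
    vapply(seq_len(ncol(pr)), function(k) {
      pairwise_r2(cohort$dosage[, pr[1, k]], cohort$dosage[, pr[2, k]])
    }, numeric(1))
  })
  within <- unlist(within)
  tibble(
    mean_adjacent_within_r2 = mean(r2_adj_within),
    mean_within_block_r2 = mean(within),
    mean_adjacent_cross_r2 = if (length(r2_adj_cross)) mean(r2_adj_cross) else NA_real_,
    n_within_pairs = length(within),
    n_cross_pairs = length(r2_adj_cross)
  )
}
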