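test_that("logistic beta equals the 2x2 log odds ratio on a binary dosage", {
  # dosage 1: 20 cases / 10 controls; dosage 0: 10 cases / 20 controls
  d <- rep(c(1, 0), each = 30)
  y <- rep(c("case", "control", "case", "control"), c(20, 10, 10, 20))
  fit <- fit_snp_logistic(d, y)
  expect_equal(fit$beta, log(4), tolerance = 1e-7)
  expect_equal(fit$odds_ratio, 4, tolerance = 1e-6)
  expect_true(fit$usable)

  # association-free balanced table
  d0 <- rep(c(1, 0), each = 20)
  y0 <- rep(c("case", "control"), 20)
  expect_equal(fit_snp_logistic(d0, y0)$beta, 0, tolerance = 1e-9)
})

test_that("logistic fits match glm across random datasets and flag separation", {
  set.seed(19)
  n_checked <- 0
  for (i in 1:150) {
    n <- sample(25:70, 1)
    d <- sample(0:2, n, TRUE, prob = c(0.5, 0.35, 0.15))
    y <- rbinom(n, 1, plogis(-0.4 + 0.5 * d))
    if (length(unique(d)) < 2 || sum(y) < 2 || sum(1 - y) < 2) next
    fit <- fit_snp_logistic(d, y)
    if (!fit$usable) next
    ref <- suppressWarnings(glm(y ~ d, family = binomial(),
                                control = glm.control(epsilon = 1e-12)))
    expect_equal(fit$beta, unname(coef(ref)[2]), tolerance = 1e-6)
    expect_equal(fit$se, summary(ref)$coefficients[2, 2], tolerance = 1e-6)
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 100)

  # complete separation is flagged unusable
  sep <- fit_snp_logistic(c(2, 2, 2, 0, 0, 0),
                          c("case", "case", "case", "control", "control", "control"))
  expect_false(sep$usable)
  # constant dosage is flagged
  expect_false(fit_snp_logistic(rep(1, 20), rep(c("case", "control"), 10))$usable)
})

test_that("vectorized weight fitting agrees with single-SNP fits under missingness", {
  g <- random_cohort(40, 40, 12, miss = 0.1, seed = 20)
  ma <- assign_minor_alleles(g)
  w <- fit_snp_weights(g, ma)
  D <- minor_dosage(g, ma)
  for (j in which(w$usable)) {
    single <- fit_snp_logistic(D[, j], g$subjects$status)
    expect_equal(w$beta[j], single$beta, tolerance = 1e-9)
    expect_equal(w$p_value[j], single$p_value, tolerance = 1e-9)
  }
})

test_that("wGRS applies the 1x / 0.5x / 0x genotype rule", {
  base <- rbind(c(1L, 1L, 1L), c(1L, 0L, 0L), c(0L, 0L, 0L))  # controls, a1 minor
  g <- make_cohort(rbind(base, c(0L, 0L, 0L), c(0L, 1L, 0L), c(2L, 1L, 0L),
                         c(2L, NA, 0L)),
                   rep(c("control", "case"), c(3, 4)))
  ma <- assign_minor_alleles(g)
  w <- fit_snp_weights(g, ma)
  w$beta <- c(0.2, -0.4, 0.1)
  w$usable <- rep(TRUE, 3)
  s <- compute_wgrs(g, ma, w, w$snp_id)
  expect_equal(s$score[4], 0)                    # hom major everywhere
  expect_equal(s$score[5], 0.5 * -0.4)           # single het, beta -0.4
  expect_equal(s$score[6], 1 * 0.2 + 0.5 * -0.4) # dosages 2,1,0 -> 0.0
  expect_equal(s$score[6], 0)
  expect_equal(s$score[7], 0.2)                  # missing contributes 0
  expect_equal(s$n_snps_used[6:7], c(3L, 2L))
})

test_that("PRS weights dosage by log10 odds ratio", {
  base <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 0L))
  g <- make_cohort(rbind(base, c(0L, 1L), c(2L, 2L)),
                   rep(c("control", "case"), c(3, 2)))
  ma <- assign_minor_alleles(g)
  w <- fit_snp_weights(g, ma)
  w$usable <- c(TRUE, TRUE)

  w$odds_ratio <- c(1, 10)
  s <- compute_prs(g, ma, w, w$snp_id)
  expect_equal(s$score[4], 1)  # one het at OR 10 -> log10(10)
  # ORs 2 and 0.5 cancel at dosages 2,2
  w$odds_ratio <- c(2, 0.5)
  s2 <- compute_prs(g, ma, w, w$snp_id)
  expect_equal(s2$score[5], 0, tolerance = 1e-12)
})

test_that("wGRS is additive over disjoint SNP subsets", {
  g <- random_cohort(30, 30, 20, miss = 0.05, seed = 22)
  ma <- assign_minor_alleles(g)
  w <- fit_snp_weights(g, ma)
  ok <- w$snp_id[w$usable]
  a <- ok[seq(1, length(ok), 2)]
  b <- setdiff(ok, a)
  s_all <- compute_wgrs(g, ma, w, ok)
  s_a <- compute_wgrs(g, ma, w, a)
  s_b <- compute_wgrs(g, ma, w, b)
  expect_equal(s_all$score, s_a$score + s_b$score, tolerance = 1e-12)
  expect_equal(s_all$n_snps_used, s_a$n_snps_used + s_b$n_snps_used)
})

test_that("scoring contracts: empty subset, unknown SNPs, unusable weights", {
  g <- random_cohort(10, 10, 5, seed = 23)
  ma <- assign_minor_alleles(g)
  w <- fit_snp_weights(g, ma)
  expect_error(compute_wgrs(g, ma, w, character()), "empty")
  expect_error(compute_wgrs(g, ma, w, "nope"), "without trained weights")
  w2 <- w; w2$usable[1] <- FALSE
  expect_error(compute_wgrs(g, ma, w2, w2$snp_id[1]), "unusable")
})

test_that("own-weight scoring separates training classes; permutation null does not", {
  set.seed(24)
  sim <- small_sim(24, n = 100, m = 250, minor_risk_prob = 1,
                   causal_fraction = 0.1, effect_sd = 0.3)
  g1 <- sim$cohorts[[1]]
  g2 <- sim$cohorts[[2]]
  ma <- assign_minor_alleles(g1)
  w <- fit_snp_weights(g1, ma)
  ok <- w$snp_id[w$usable]
  s <- compute_wgrs(g1, ma, w, ok)
  expect_gt(mean(s$score[s$status == "case"]),
            mean(s$score[s$status == "control"]))

  # leakage canary: weights trained on permuted labels carry no signal
  aucs <- replicate(12, {
    gp <- g1
    gp$subjects$status <- sample(gp$subjects$status)
    map <- assign_minor_alleles(gp)
    wp <- fit_snp_weights(gp, map)
    sv <- compute_wgrs(g2, map, wp, wp$snp_id[wp$usable])
    score_auc(sv$score, sv$status)$auc
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.02)
})

test_that("weight and score tables round-trip through their writers", {
  g <- random_cohort(20, 20, 8, miss = 0.05, seed = 25)
  ma <- assign_minor_alleles(g)
  w <- fit_snp_weights(g, ma)
  p <- tempfile(fileext = ".tsv")
  write_snp_weights(w, p)
  w2 <- read_snp_weights(p)
  for (col in names(w)) {
    expect_equal(w2[[col]], w[[col]], tolerance = 1e-15, label = col)
  }

  s <- compute_wgrs(g, ma, w, w$snp_id[w$usable])
  p2 <- tempfile(fileext = ".tsv")
  write_scores(s, p2)
  s2 <- read_scores(p2)
  expect_equal(s2$score, s$score, tolerance = 1e-15)
  expect_identical(s2$subject_id, s$subject_id)
})
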