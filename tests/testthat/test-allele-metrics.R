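test_that("minor-allele assignment matches a per-SNP counting oracle", {
  # direct example: control dosages of a1 are 0,0,1 -> freq 1/6
  g <- make_cohort(matrix(c(2L, 0L, 0L, 1L), ncol = 1),
                   c("case", "control", "control", "control"))
  ma <- assign_minor_alleles(g)
  expect_equal(ma$maf, 1 / 6, tolerance = 1e-12)
  expect_identical(ma$minor_allele, "A")  # a1 is the rarer allele

  # frequency exactly 0.5 is a tie: non-informative
  tie <- make_cohort(matrix(c(1L, 1L, 0L, 2L), ncol = 1),
                     rep("control", 4))
  expect_false(assign_minor_alleles(tie)$informative)

  # monomorphic and all-missing SNPs are non-informative
  degen <- make_cohort(cbind(rep(0L, 4), rep(NA_integer_, 4)),
                       rep(c("case", "control"), 2))
  expect_identical(assign_minor_alleles(degen)$informative, c(FALSE, FALSE))

  # 20-SNP random fixture vs brute-force allele counting in controls
  g <- random_cohort(15, 25, 20, miss = 0.1, seed = 31)
  ma <- assign_minor_alleles(g)
  ctrl <- g$subjects$status == "control"
  for (j in 1:20) {
    x <- g$dosage[ctrl, j]
    n_a1 <- sum(x, na.rm = TRUE)
    n_tot <- 2 * sum(!is.na(x))
    f1 <- n_a1 / n_tot
    if (f1 == 0.5 || f1 %in% c(0, 1)) {
      expect_false(ma$informative[j])
    } else {
      expect_equal(ma$maf[j], min(f1, 1 - f1), tolerance = 1e-12)
      expect_identical(ma$minor_allele[j],
                       if (f1 < 0.5) g$snps$a1[j] else g$snps$a2[j])
    }
  }
})

test_that("MAC normalization anchors and hand-computed sums", {
  # 3 controls make a1 the minor allele at every SNP, subjects 4-6 probe
  base <- rbind(c(1L, 1L, 1L), c(1L, 0L, 0L), c(0L, 0L, 0L))
  probe <- rbind(c(0L, 0L, 0L),   # hom major everywhere -> MAC 0
                 c(1L, 1L, 1L),   # het everywhere -> 0.5
                 c(2L, 2L, 2L))   # hom minor everywhere -> 1
  g <- make_cohort(rbind(base, probe),
                   rep(c("control", "case"), each = 3))
  mac <- compute_mac(g, assign_minor_alleles(g))
  expect_equal(mac$mac[4:6], c(0, 0.5, 1))

  # dosages 0,1,2 over 3 SNPs -> 3/6; with one missing -> 1/4
  g2 <- make_cohort(rbind(base, c(0L, 1L, 2L), c(0L, NA, 1L)),
                    rep(c("control", "case"), c(3, 2)))
  mac2 <- compute_mac(g2, assign_minor_alleles(g2))
  expect_equal(mac2$mac[4:5], c(0.5, 0.25))
  expect_equal(mac2$n_used[4:5], c(3L, 2L))

  # literal per-SNP denominator doubles the values
  mac3 <- compute_mac(g2, assign_minor_alleles(g2), denominator = "snps")
  expect_equal(mac3$mac[4:5], c(1, 0.5))
})

test_that("MAC is invariant to SNP order and to the stored counted allele", {
  g <- random_cohort(20, 30, 25, miss = 0.05, seed = 41)
  mac <- compute_mac(g, assign_minor_alleles(g))

  perm <- sample(25)
  gp <- subset_cohort(g, snps = perm)
  macp <- compute_mac(gp, assign_minor_alleles(gp))
  expect_equal(macp$mac, mac$mac)

  # relabel the counted allele at half the SNPs: dosage d -> 2 - d
  flip <- seq(1, 25, by = 2)
  d2 <- g$dosage
  d2[, flip] <- 2L - d2[, flip, drop = FALSE]
  snps2 <- g$snps
  snps2[flip, c("a1", "a2")] <- snps2[flip, c("a2", "a1")]
  gf <- geno_cohort(d2, snps2, g$subjects)
  macf <- compute_mac(gf, assign_minor_alleles(gf))
  expect_equal(macf$mac, mac$mac)
})

test_that("expected MAC of Hardy-Weinberg subjects matches the mean panel MAF", {
  sim <- small_sim(51, n = 400, m = 150, causal_fraction = 0,
                   missing_rate = 0)
  g <- sim$cohorts[[1]]
  ma <- assign_minor_alleles(g)
  mac <- compute_mac(g, ma)
  expect_equal(mean(mac$mac), mean(ma$maf[ma$informative]),
               tolerance = 0.01)
})

test_that("two-sample z matches the closed form and is antisymmetric", {
  z <- two_sample_z(c(1, 2, 3), c(4, 5, 6))
  expect_equal(z$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(z$statistic, -3.674, tolerance = 1e-3)
  expect_equal(z$p_value, 2.39e-4, tolerance = 1e-2)
  expect_equal(z$sem_a, sqrt(1 / 3), tolerance = 1e-12)

  ident <- two_sample_z(c(2, 3, 4), c(2, 3, 4))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  const <- suppressWarnings(two_sample_z(c(1, 1), c(2, 2)))
  expect_true(is.infinite(const$statistic) && const$p_value == 0)

  set.seed(6)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(12, 0.5)
    expect_equal(two_sample_z(a, b)$statistic,
                 -two_sample_z(b, a)$statistic, tolerance = 1e-12)
    p <- two_sample_z(a, b)$p_value
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("two-sample z rejects at the nominal rate under the null", {
  set.seed(7)
  n_rep <- 4000
  a <- matrix(rnorm(n_rep * 50), n_rep)
  b <- matrix(rnorm(n_rep * 50), n_rep)
  zs <- (rowMeans(a) - rowMeans(b)) /
    sqrt(apply(a, 1, var) / 50 + apply(b, 1, var) / 50)
  # sanity of the vectorized oracle against the function on a few rows
  for (i in 1:5) {
    expect_equal(two_sample_z(a[i, ], b[i, ])$statistic, zs[i],
                 tolerance = 1e-12)
  }
  rate <- mean(2 * pnorm(-abs(zs)) < 0.05)
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / n_rep) - 0.005)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep) + 0.005)
})

test_that("F-test matches the F(2,2) closed form and is symmetric", {
  ft <- f_test_variance(c(1, 2, 3), c(2, 4, 6))
  expect_equal(ft$statistic, 4)
  expect_equal(ft$p_value, 0.4, tolerance = 1e-12)  # F(2,2): P(F>x) = 1/(1+x)

  eq <- f_test_variance(c(1, 2, 3), c(4, 5, 6))
  expect_equal(eq$statistic, 1)
  expect_equal(eq$p_value, 1)

  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(9, sd = 2)
    expect_equal(f_test_variance(a, b)$p_value,
                 f_test_variance(b, a)$p_value, tolerance = 1e-12)
  }
  expect_warning(out <- f_test_variance(c(1, 1, 1), c(1, 2, 3)), "infinite")
  expect_true(is.infinite(out$statistic))
})

test_that("two-proportion chi-square matches the Pearson closed form", {
  same <- chi2_two_proportions(10, 100, 10, 100)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  ex <- chi2_two_proportions(20, 100, 10, 100)
  expect_equal(ex$statistic, 200 * (20 * 90 - 80 * 10)^2 /
                 (100 * 100 * 30 * 170), tolerance = 1e-12)
  expect_equal(ex$statistic, 3.922, tolerance = 1e-3)
  expect_equal(ex$p_value, 0.0477, tolerance = 1e-2)

  expect_warning(deg <- chi2_two_proportions(0, 50, 0, 80), "degenerate")
  expect_equal(deg$p_value, 1)

  # random tables vs the closed-form 2x2 Pearson statistic
  set.seed(9)
  for (i in 1:300) {
    n1 <- sample(10:200, 1); n2 <- sample(10:200, 1)
    x1 <- rbinom(1, n1, 0.3); x2 <- rbinom(1, n2, 0.4)
    if ((x1 + x2) %in% c(0, n1 + n2)) next
    got <- chi2_two_proportions(x1, n1, x2, n2)
    nn <- n1 + n2
    chi <- nn * (x1 * (n2 - x2) - (n1 - x1) * x2)^2 /
      (n1 * n2 * (x1 + x2) * (nn - x1 - x2))
    expect_equal(got$statistic, chi, tolerance = 1e-10)
    expect_equal(got$p_value, pchisq(chi, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})
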