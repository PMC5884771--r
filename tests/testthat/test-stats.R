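test_that("Spearman correlation equals Pearson of midranks, with sane p-values", {
  # strictly monotone, tie-free pair
  x <- c(3, 9, 1, 7, 5, 11)
  expect_equal(unname(spearman_cor(x, x^3)$estimate), 1)

  # tie-heavy vectors against the midrank oracle
  set.seed(42)
  for (i in 1:20) {
    a <- sample(1:4, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    res <- spearman_cor(a, b)
    ra <- rank(a); rb <- rank(b)
    oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
    expect_equal(unname(res$estimate), oracle, tolerance = 1e-12)
  }

  # t-approximation p matches base cor.test on tie-free data
  set.seed(7)
  a <- rnorm(12); b <- a + rnorm(12)
  expect_equal(spearman_cor(a, b)$p.value,
               cor.test(a, b, method = "spearman", exact = FALSE)$p.value,
               tolerance = 1e-10)

  expect_error(spearman_cor(rep(1, 6), 1:6), "constant")
  expect_error(spearman_cor(1:3, 1:3), "at least 4")

  # permutation p is a valid p-value under the null
  set.seed(1)
  p <- spearman_cor(rnorm(10), rnorm(10), p_method = "permutation",
                    n_perm = 500)$p.value
  expect_gte(p, 0); expect_lte(p, 1)
})

test_that("exact Mann-Whitney enumeration matches brute force and base R", {
  # frozen small cases
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  expect_equal(mann_whitney_exact(c(2, 5, 9), c(2, 5, 9))$p.value, 1)

  # random tie-heavy inputs, total n <= 12, against the pairwise-U oracle
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- sample(1:5, n1, replace = TRUE)
    b <- sample(1:5, n2, replace = TRUE)
    expect_equal(mann_whitney_exact(a, b)$p.value,
                 oracle_mw_p_two_sided(a, b), tolerance = 1e-12)
  }

  # tie-free inputs also agree with base wilcox.test exact p
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(6)
    expect_equal(mann_whitney_exact(a, b)$p.value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }

  expect_error(mann_whitney_exact(rnorm(12), rnorm(12)),
               "exceeds the enumeration cap")
  expect_error(mann_whitney_exact(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney type-I error is calibrated at the attainable level", {
  # the exact test is discrete: under the null with continuous data the
  # rejection probability at alpha = 0.05 is the attainable level, computed
  # here from the permutation distribution of U for tie-free ranks
  n1 <- 6; n2 <- 6
  r <- seq_len(n1 + n2)
  us <- colSums(matrix(r[utils::combn(n1 + n2, n1)], nrow = n1)) -
    n1 * (n1 + 1) / 2
  p_of_u <- vapply(us, function(u)
    min(1, 2 * min(mean(us <= u), mean(us >= u))), 1.0)
  alpha_star <- mean(p_of_u <= 0.05)
  expect_lte(alpha_star, 0.05)

  set.seed(2024)
  reps <- 200
  rejections <- sum(replicate(reps, {
    mann_whitney_exact(rnorm(n1), rnorm(n2))$p.value <= 0.05
  }))
  bounds <- qbinom(c(0.025, 0.975), reps, alpha_star)
  expect_gte(rejections, bounds[1])
  expect_lte(rejections, bounds[2])
})

test_that("Fisher's exact test matches the hypergeometric oracle and base R", {
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2), "two.sided")$p.value, 1)
  # advanced-stage contingency: upper tail 176/3432
  tab <- matrix(c(5, 2, 1, 6), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab, "one.sided")$p.value, 176 / 3432,
               tolerance = 1e-12)

  # all 2x2 tables with cells <= 3 and no empty margin, vs direct summation
  # and base fisher.test
  for (a in 0:3) for (b in 0:3) for (cc in 0:3) for (d in 0:3) {
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    m <- a + b; n <- cc + d; k <- a + cc
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    oracle_one <- if (a >= k * m / (m + n)) sum(probs[support >= a])
                  else sum(probs[support <= a])
    expect_equal(fisher_exact(tab, "one.sided")$p.value, oracle_one,
                 tolerance = 1e-12)
    expect_equal(fisher_exact(tab, "two.sided")$p.value,
                 fisher.test(tab)$p.value, tolerance = 1e-7)
  }

  # one-sided never exceeds two-sided
  set.seed(3)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 4) + 1, 2)
    expect_lte(fisher_exact(tab, "one.sided")$p.value,
               fisher_exact(tab, "two.sided")$p.value + 1e-12)
  }

  expect_error(fisher_exact(matrix(c(0, 0, 2, 3), 2, byrow = TRUE)),
               "empty margin")
})

test_that("paired Wilcoxon enumeration matches brute force and base R", {
  # constant positive shift, n = 6: most extreme of 2^6 sign patterns
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0, 6.3)
  expect_equal(wilcoxon_paired(x + 1, x)$p.value, 2 / 64)
  expect_error(wilcoxon_paired(x, x), "degenerate")

  set.seed(21)
  for (i in 1:30) {
    n <- sample(4:9, 1)
    a <- sample(1:6, n, replace = TRUE)
    b <- sample(1:6, n, replace = TRUE)
    if (all(a == b)) next
    expect_equal(wilcoxon_paired(a, b)$p.value,
                 oracle_wilcoxon_p_two_sided(a, b), tolerance = 1e-12)
  }

  # tie-free agreement with base wilcox.test exact p
  set.seed(22)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(wilcoxon_paired(a, b)$p.value,
                 wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }

  # large-sample branch reports the normal approximation
  big <- wilcoxon_paired(rnorm(30), rnorm(30))
  expect_match(big$method, "normal approximation")
  expect_gte(big$p.value, 0); expect_lte(big$p.value, 1)
})

test_that("ICC agreement matches the mean-squares oracle and bands correctly", {
  # identical raters on varying subjects: perfect agreement
  r <- cbind(1:6, 1:6, 1:6)
  res <- icc_agreement(r, model = "inter")
  expect_equal(res$icc, 1)
  expect_equal(res$band, "excellent")

  # constructed matrix vs the explicit variance-components formula
  ratings <- cbind(r1 = c(1, 2, 3, 4, 5), r2 = c(2, 3, 4, 5, 6))
  res <- icc_agreement(ratings, model = "inter")
  ns <- nrow(ratings); nr <- ncol(ratings)
  grand <- mean(ratings)
  ssr <- nr * sum((rowMeans(ratings) - grand)^2)
  ssc <- ns * sum((colMeans(ratings) - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (ns - 1); msc <- ssc / (nr - 1)
  mse <- sse / ((ns - 1) * (nr - 1))
  oracle <- (msr - mse) / (msr + (nr - 1) * mse + nr * (msc - mse) / ns)
  expect_equal(res$icc, oracle, tolerance = 1e-10)
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)

  # noisy independent columns on random subjects: ICC drops below 1
  set.seed(31)
  iccs <- replicate(50, {
    subj <- rnorm(8, sd = 2)
    icc_agreement(cbind(subj, subj + rnorm(8)), model = "inter")$icc
  })
  expect_true(all(iccs < 1))
  expect_lt(mean(iccs), 0.95)

  # intra model: one-way random; duplicated repeats give 1
  expect_equal(icc_agreement(cbind(1:7, 1:7), model = "intra")$icc, 1)

  # agreement bands from the lower CI bound (inclusive 0.50/0.75 bounds,
  # excellent strictly above 0.90)
  band <- semiqaf:::icc_band_label
  expect_equal(band(0.944), "excellent")
  expect_equal(band(0.90), "good")
  expect_equal(band(0.75), "good")
  expect_equal(band(0.50), "moderate")
  expect_equal(band(0.49), "poor")

  expect_error(icc_agreement(matrix(5, 6, 2), model = "inter"), "variance")
  expect_error(icc_agreement(matrix(rnorm(8), 4, 2)), "at least 5")
})

test_that("cohort correlation matrix is symmetric and handles degenerate columns", {
  g <- gen_cohort(24, seed = 9, images = FALSE)
  cm <- suppressWarnings(correlation_matrix(g$cohort))
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(cm$p, t(cm$p))
  expect_true(all(diag(cm$rho) == 1))
  # constant column (bcva is constant in simulated cohorts) is skipped
  expect_false("bcva_logmar" %in% rownames(cm$rho))
  expect_warning(correlation_matrix(g$cohort), "bcva_logmar")
})

test_that("NIR-AF group comparison splits and tests as specified", {
  achm <- fixture_table2()
  res <- nir_group_analysis(achm)
  expect_equal(unname(res$age_present["n"]), 7)
  expect_equal(unname(res$age_absent["n"]), 7)
  expect_equal(res$n_borderline, 2L)
  expect_equal(unname(res$stage_table[1, ]), c(5, 2))
  expect_equal(unname(res$stage_table[2, ]), c(1, 6))

  # identical age distributions: MW p = 1
  same <- make_test_cohort(c(10, 20, 30), c(10, 20, 30))
  expect_equal(nir_group_analysis(same)$mann_whitney$p.value, 1)

  # two-sided Fisher is the doubled-tail-free convention, larger than one-sided
  expect_gte(nir_group_analysis(achm, "two.sided")$fisher$p.value,
             res$fisher$p.value)

  expect_error(nir_group_analysis(make_test_cohort(25, c(10, 20, 30))),
               "at least 2")
})
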