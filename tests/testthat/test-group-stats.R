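# Direct-formula oracles, written inline and independent of the package
# implementations.
oracle_anova_f <- function(groups) {
  k <- length(groups); n <- lengths(groups); N <- sum(n)
  grand <- mean(unlist(groups))
  ssb <- sum(n * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  (ssb / (k - 1)) / (ssw / (N - k))
}

test_that("one-way ANOVA matches sums-of-squares and t^2 oracles", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  a <- one_way_anova(g)
  expect_equal(a$statistic, 3)                       # frozen fixture value
  expect_identical(a$df, c(2L, 6L))
  expect_equal(a$statistic, oracle_anova_f(g), tolerance = 1e-12)
  # identical means, nonzero spread -> F = 0
  a0 <- one_way_anova(list(c(-1, 1), c(-2, 2), c(-3, 3)))
  expect_equal(a0$statistic, 0)
  # two groups: F = t^2 (pooled-variance t)
  set.seed(1)
  x <- rnorm(12); y <- rnorm(10, 0.7)
  f2 <- one_way_anova(list(x, y))$statistic
  t2 <- unname(t.test(x, y, var.equal = TRUE)$statistic^2)
  expect_equal(f2, t2, tolerance = 1e-10)
  # random fixtures against the oracle
  for (i in 1:20) {
    g <- replicate(sample(2:5, 1), rnorm(sample(3:9, 1), runif(1)),
                   simplify = FALSE)
    expect_equal(one_way_anova(g)$statistic, oracle_anova_f(g), tolerance = 1e-8)
  }
  expect_error(one_way_anova(list(1:3)), "2 groups")
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "zero within-group")
})

test_that("Tukey HSD q follows the direct formula and is conservative", {
  set.seed(2)
  g <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 2))
  tk <- tukey_hsd(g)
  a <- one_way_anova(g)
  for (r in seq_len(nrow(tk))) {
    mi <- mean(g[[tk$group1[r]]]); mj <- mean(g[[tk$group2[r]]])
    q_ref <- abs(mi - mj) / sqrt(a$ms_within / 6)
    expect_equal(tk$q[r], q_ref, tolerance = 1e-8)
    # adjusted p never below the unadjusted pairwise p (equal n)
    p_raw <- t.test(g[[tk$group1[r]]], g[[tk$group2[r]]],
                    var.equal = TRUE)$p.value
    expect_gte(tk$p_adj[r] + 1e-12, p_raw * 0.999)
  }
  # identical groups -> q = 0, p = 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  tk0 <- tukey_hsd(same)
  expect_true(all(tk0$q == 0))
  expect_true(all(tk0$p_adj == 1))
  expect_true(all(tk0$p_adj >= 0 & tk0$p_adj <= 1))
})

test_that("studentized range CDF agrees with R's ptukey to 1e-5", {
  for (q in c(0.3, 1, 2.2, 3.7, 5.5)) for (k in c(2, 3, 5)) for (df in c(4, 15, 120)) {
    expect_equal(studentized_range_cdf(q, k, df), stats::ptukey(q, k, df),
                 tolerance = 1e-5)
  }
  expect_equal(studentized_range_cdf(0, 3, 10), 0)
  expect_equal(studentized_range_cdf(2, 3, Inf), stats::ptukey(2, 3, Inf),
               tolerance = 1e-6)
})

test_that("repeated-measures ANOVA removes the subject effect", {
  # 4 subjects x 3 conditions fixture against the partitioned-SS oracle
  set.seed(3)
  tab <- matrix(rnorm(12, rep(c(0, 1, 0.3), each = 4)), 4, 3)
  a <- rm_one_way_anova(tab)
  grand <- mean(tab)
  ss_s <- 3 * sum((rowMeans(tab) - grand)^2)
  ss_c <- 4 * sum((colMeans(tab) - grand)^2)
  ss_e <- sum((tab - grand)^2) - ss_s - ss_c
  f_ref <- (ss_c / 2) / (ss_e / 6)
  expect_equal(a$statistic, f_ref, tolerance = 1e-10)
  expect_identical(a$df, c(2L, 6L))
  # equal condition means -> F = 0
  t0 <- cbind(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  expect_equal(rm_one_way_anova(t0)$statistic, 0, tolerance = 1e-12)
  # adding a per-subject constant leaves F unchanged
  shifted <- tab + c(10, -5, 3, 100)
  expect_equal(rm_one_way_anova(shifted)$statistic, a$statistic, tolerance = 1e-9)
  tab[2, 3] <- NA
  expect_error(rm_one_way_anova(tab), "incomplete")
})

test_that("Pearson r matches the product-moment formula with regression extras", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cor(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_cor(x, -x)$statistic, -1)
  y <- c(2, 1, 4, 3, 5)
  r_ref <- sum((x - 3) * (y - 3)) / sqrt(sum((x - 3)^2) * sum((y - 3)^2))
  res <- pearson_cor(x, y)
  expect_equal(res$statistic, r_ref, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(res$statistic, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-10)
  lmfit <- lm(y ~ x)
  expect_equal(res$slope, unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(res$intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("Shapiro-Wilk W matches the coefficient-algorithm reference", {
  # frozen n = 12 fixture; reference W computed independently from the
  # published coefficient algorithm (R's shapiro.test implementation)
  x12 <- c(-1.21, -0.74, -0.52, -0.31, -0.12, 0.05, 0.18, 0.42, 0.66,
           0.91, 1.20, 1.85)
  ref <- shapiro.test(x12)
  res <- shapiro_wilk(x12)
  expect_equal(res$statistic, 0.9925778, tolerance = 1e-3)  # frozen reference
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-3)
  expect_equal(res$p_value, ref$p.value, tolerance = 5e-3)
  # near-perfect normal quantile sequence -> W > 0.99
  q <- qnorm(ppoints(200))
  expect_gt(shapiro_wilk(q)$statistic, 0.99)
  # affine invariance
  set.seed(4)
  z <- rnorm(25)
  expect_equal(shapiro_wilk(z)$statistic, shapiro_wilk(3.7 * z - 11)$statistic,
               tolerance = 1e-12)
  expect_error(shapiro_wilk(rep(1, 10)), "zero variance")
  expect_error(shapiro_wilk(1:2), "3 <= n")
  # W stays in (0, 1] and p in [0, 1] across assorted samples
  for (i in 1:10) {
    s <- shapiro_wilk(rexp(sample(5:60, 1)))
    expect_true(s$statistic > 0 && s$statistic <= 1)
    expect_true(s$p_value >= 0 && s$p_value <= 1)
  }
})
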