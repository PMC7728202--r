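test_that("gated comparison takes the t branch for Gaussian samples and matches the t oracle", {
  set.seed(10)
  a <- rnorm(20, 0, 1)
  b <- rnorm(20, 2, 1)
  r <- gated_compare(a, b)
  expect_equal(r$test_used, "t_test")
  expect_gte(r$normality_p_a, 0.05)
  expect_equal(r$p_two_sided, oracle_t_p(a, b), tolerance = 1e-8)
  expect_equal(r$mean_a, mean(a))
  expect_equal(r$sem_a, sd(a) / sqrt(20))
})

test_that("an outlier breaks normality and routes to Mann-Whitney", {
  set.seed(11)
  a <- rnorm(15)
  b <- c(rnorm(14), 40)  # one extreme outlier
  expect_lt(shapiro.test(b)$p.value, 0.05)
  r <- gated_compare(a, b)
  expect_equal(r$test_used, "mann_whitney")
})

test_that("identical samples compare as indistinguishable", {
  set.seed(12)
  a <- rnorm(12)
  r <- gated_compare(a, a)
  expect_gt(r$p_two_sided, 0.99)
  # all-constant identical samples: Shapiro undefined, p = 1
  expect_warning(rc <- gated_compare(rep(3, 5), rep(3, 6)), "zero-variance")
  expect_equal(rc$test_used, "mann_whitney")
  expect_equal(rc$p_two_sided, 1)
})

test_that("t-branch p-values are shift invariant; MW branch is monotone invariant", {
  set.seed(13)
  a <- rnorm(10); b <- rnorm(10, 0.5)
  p1 <- gated_compare(a, b)$p_two_sided
  p2 <- gated_compare(a + 7, b + 7)$p_two_sided
  expect_equal(p1, p2)
  a2 <- rlnorm(12, 0, 1); b2 <- c(rlnorm(11, 1, 1), 80)
  r1 <- gated_compare(a2, b2)
  r2 <- gated_compare(log(a2), log(b2))
  if (r1$test_used == "mann_whitney" && r2$test_used == "mann_whitney")
    expect_equal(r1$p_two_sided, r2$p_two_sided)
  expect_equal(suppressWarnings(wilcox.test(a2, b2)$p.value),
               suppressWarnings(wilcox.test(exp(a2), exp(b2))$p.value))
})

test_that("exact and approximate Mann-Whitney p-values agree for large tie-free samples", {
  set.seed(14)
  a <- rnorm(60); b <- rnorm(60, 0.2)
  p_exact <- wilcox.test(a, b, exact = TRUE)$p.value
  p_approx <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(p_exact - p_approx), 0.005)
})

test_that("chi-square on the abnormal-proportion table matches the hand computation", {
  tab <- matrix(c(8, 2, 17, 26), 2)  # 8/25 vs 2/28 abnormal
  r <- chi_square_2x2(tab)
  # hand computation of sum (O - E)^2 / E from the printed counts
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_hand <- sum((tab - E)^2 / E)
  expect_equal(r$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(round(stat_hand, 2), 5.33)
  # p from the df = 1 chi-square via the normal CDF (independent route)
  expect_equal(r$p_two_sided, 2 * pnorm(-sqrt(stat_hand)), tolerance = 1e-12)
  expect_equal(round(r$p_two_sided, 2), 0.02)
})

test_that("chi-square is invariant under transposition and joint row/col swaps", {
  tab <- matrix(c(8, 2, 17, 26), 2)
  r <- chi_square_2x2(tab)
  expect_equal(chi_square_2x2(t(tab))$statistic, r$statistic)
  swapped <- tab[2:1, 2:1]
  expect_equal(chi_square_2x2(swapped)$statistic, r$statistic)
  flat <- matrix(c(5, 5, 5, 5), 2)
  r0 <- chi_square_2x2(flat)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_two_sided, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("regression recovers exact fits and matches the normal-equations oracle", {
  x <- 1:10
  r <- lin_regress(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)

  # orthogonal construction: sum((x - mean)(y - mean)) = 0 gives slope 0
  x0 <- c(-1, 0, 1)
  y0 <- c(1, -2, 1)
  expect_equal(sum((x0 - mean(x0)) * (y0 - mean(y0))), 0)
  expect_equal(lin_regress(x0, y0)$slope, 0)

  set.seed(15)
  xn <- runif(25, 0, 10)
  yn <- 0.5 * xn + rnorm(25)
  rn <- lin_regress(xn, yn)
  o <- oracle_ols(xn, yn)
  expect_equal(rn$slope, o$slope, tolerance = 1e-10)
  expect_equal(rn$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(rn$r_squared, cor(xn, yn)^2)

  expect_error(lin_regress(rep(2, 5), rnorm(5)), "constant predictor")
  rc <- lin_regress(1:5, rep(3, 5))
  expect_equal(rc$slope, 0)
  expect_equal(rc$r_squared, 0)
  expect_equal(rc$p_two_sided, 1)
})

test_that("R^2 is invariant under affine rescaling of either variable", {
  set.seed(16)
  x <- rnorm(30); y <- 0.8 * x + rnorm(30)
  r0 <- lin_regress(x, y)$r_squared
  expect_equal(lin_regress(3 * x - 5, y)$r_squared, r0)
  expect_equal(lin_regress(x, -2 * y + 11)$r_squared, r0)
})

test_that("the detector threshold is the two-sided 99% normal critical value", {
  expect_equal(round(normal_critical_value(0.01), 3), 2.576)
  expect_equal(normal_critical_value(0.05), qnorm(0.975))
})
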