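test_that("chi-squared goodness of fit from observed/expected counts", {
  t0 <- chi2_gof(c(10, 20, 30), c(10, 20, 30))
  expect_equal(t0$value, 0)
  expect_equal(t0$p, 1)
  t1 <- chi2_gof(c(10, 0), c(5, 5))
  expect_equal(t1$value, 10)
  expect_equal(t1$df, 1L)
  # pair-class table built from genome-wide fractions: direct summation
  t2 <- chi2_gof(c(187, 103, 0), c(164.31, 107.96, 17.73))
  expect_lt(abs(t2$value - 21.0), 0.4)
  expect_equal(t2$df, 2L)
  expect_error(chi2_gof(c(1, 2), c(0, 3)), "positive")
})

test_that("Yates-corrected 2x2 test reproduces printed p-values", {
  p1 <- chi2_2x2_yates(matrix(c(702, 150, 3405, 895), 2, byrow = TRUE))
  expect_equal(round(p1$p, 4), 0.0374)
  p4 <- chi2_2x2_yates(matrix(c(480, 169, 2421, 1226), 2, byrow = TRUE))
  expect_equal(round(p4$p, 4), 0.0002)
  sym <- chi2_2x2_yates(matrix(10, 2, 2))
  expect_equal(sym$value, 0)
  expect_equal(sym$p, 1)
})

test_that("Yates test is invariant to transpose and row/column swaps and
           agrees with the base implementation", {
  set.seed(5)
  for (i in 1:25) {
    tab <- matrix(sample(5:500, 4), 2, 2)
    a <- chi2_2x2_yates(tab)
    expect_equal(chi2_2x2_yates(t(tab))$value, a$value)
    expect_equal(chi2_2x2_yates(tab[2:1, 2:1])$value, a$value)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(a$value, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(a$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("equal-variance t-test matches the hand formula", {
  a <- c(1, 2, 3)
  b <- a + 10
  tt <- t_test_ind(a, b)
  # mean difference 10, pooled sd 1, se = sqrt(2/3)
  expect_equal(abs(tt$value), 10 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(tt$df, 4L)
  expect_equal(t_test_ind(b, a)$value, -tt$value)
  expect_equal(t_test_ind(b, a)$p, tt$p)
  same <- t_test_ind(c(1, 1, 2), c(1, 1, 2))
  expect_equal(same$value, 0)
  ident <- t_test_ind(c(2, 2), c(2, 2))
  expect_equal(ident$p, 1)
})

test_that("one-way ANOVA is the square of the two-sample t-test", {
  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    f <- anova_oneway(list(a, b))
    t <- t_test_ind(a, b)
    expect_equal(f$value, t$value^2, tolerance = 1e-9)
    expect_equal(f$p, t$p, tolerance = 1e-9)
  }
  z <- anova_oneway(list(c(3, 3, 3), c(3, 3), c(3, 3, 3, 3)))
  expect_equal(z$value, 0)
  expect_equal(z$p, 1)
})

test_that("reported tail probabilities agree with direct integration of
           the chi-squared density", {
  dens <- function(x, df) x^(df / 2 - 1) * exp(-x / 2) /
    (2^(df / 2) * gamma(df / 2))
  e <- 100
  for (df in 1:2) {
    for (x in c(0.5, 1, 3.84, 10, 21.9, 50)) {
      d <- sqrt(x * e / 2)
      obs <- if (df == 1) c(e + d, e - d) else c(e + d, e - d, e)
      res <- chi2_gof(obs, rep(e, df + 1))
      expect_equal(res$value, x, tolerance = 1e-9)
      direct <- stats::integrate(dens, x, Inf, df = df,
                                 rel.tol = 1e-13)$value
      expect_equal(res$p, direct, tolerance = 1e-10)
    }
  }
})
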