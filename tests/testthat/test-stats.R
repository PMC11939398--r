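test_that("simple regression matches the normal-equations oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  r <- linear_regression_f(x, y)
  # brute-force normal equations
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(r$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r$slope, beta[2], tolerance = 1e-10)
  res <- y - X %*% beta
  ss_res <- sum(res^2)
  ss_reg <- sum((X %*% beta - mean(y))^2)
  f_oracle <- ss_reg / (ss_res / (length(x) - 2))
  expect_equal(r$f_statistic, f_oracle, tolerance = 1e-10)
  expect_equal(r$df, c(1, 4))
})

test_that("regression degenerate cases are handled", {
  r <- linear_regression_f(1:5, 2 * (1:5) + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  expect_equal(r$p_value, 0)
  rc <- linear_regression_f(1:6, rep(3, 6))
  expect_equal(rc$slope, 0)
  expect_equal(rc$f_statistic, 0)
  expect_equal(rc$p_value, 1)
  expect_error(linear_regression_f(rep(2, 5), 1:5), "degenerate")
  expect_error(linear_regression_f(1:2, 1:2), "at least 3")
})

test_that("one-way ANOVA matches the hand decomposition", {
  a <- one_way_anova(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  # hand decomposition: between SS 13.5 on 1 df, within SS 4 on 4 df
  expect_equal(a$f_statistic, (13.5 / 1) / (4 / 4), tolerance = 1e-12)
  expect_equal(a$df, c(1, 4))
  expect_equal(unname(a$group_means), c(2, 5))
  # shift invariance
  b <- one_way_anova(list(g1 = c(1, 2, 3) + 100, g2 = c(4, 5, 6) + 100))
  expect_equal(b$f_statistic, a$f_statistic, tolerance = 1e-9)
  # identical groups
  z <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(z$f_statistic, 0)
  expect_equal(z$p_value, 1)
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "at least 2")
  # two groups of seven reproduce the experiment's (1, 12) layout
  set.seed(7)
  d <- one_way_anova(list(a = rnorm(7), b = rnorm(7)))
  expect_equal(d$df, c(1, 12))
})

test_that("multiple regression matches the pseudo-inverse oracle", {
  set.seed(11)
  X <- matrix(rnorm(60), 20, 3)
  beta_true <- c(3, 2, -1, 0.5)
  y <- beta_true[1] + X %*% beta_true[-1] + rnorm(20, sd = 0.3)
  m <- multiple_regression(X, y)
  Xa <- cbind(1, X)
  beta_pinv <- solve(t(Xa) %*% Xa) %*% t(Xa) %*% y
  expect_equal(unname(m$coefficients), c(beta_pinv), tolerance = 1e-10)
  # exact recovery with zero noise
  y0 <- 3 + 2 * X[, 1] - 1 * X[, 2]
  m0 <- multiple_regression(X[, 1:2], y0)
  expect_equal(unname(m0$coefficients), c(3, 2, -1), tolerance = 1e-10)
  # single-predictor design reproduces the simple regression
  x <- rnorm(15); yy <- 1 + 0.5 * x + rnorm(15, sd = 0.2)
  m1 <- multiple_regression(cbind(x = x), yy)
  r1 <- linear_regression_f(x, yy)
  expect_equal(unname(m1$coefficients[2]), r1$slope, tolerance = 1e-12)
  expect_equal(m1$f_statistic, r1$f_statistic, tolerance = 1e-9)
  # collinearity names the offending column
  expect_error(multiple_regression(cbind(a = x, b = 2 * x), yy),
               "collinearity.*b")
})

test_that("F tail probabilities agree with numeric density integration", {
  set.seed(3)
  cases <- data.frame(f = runif(20, 0.1, 8),
                      d1 = sample(1:4, 20, replace = TRUE),
                      d2 = sample(4:30, 20, replace = TRUE))
  for (i in seq_len(nrow(cases))) {
    f <- cases$f[i]; d1 <- cases$d1[i]; d2 <- cases$d2[i]
    tail_num <- stats::integrate(function(x) stats::df(x, d1, d2), f, Inf,
                                 rel.tol = 1e-10)$value
    expect_equal(stats::pf(f, d1, d2, lower.tail = FALSE), tail_num,
                 tolerance = 1e-6)
  }
})
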