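test_that("d agrees between sum form and quadratic form, with hand values", {
  expect_equal(dw_statistic(c(1, 1, 1, 1))$d, 0)
  dd <- dw_statistic(c(1, -1, 1, -1))
  expect_equal(dd$d, 3)
  expect_equal(dd$ssrfd, 12)
  expect_equal(dd$ssr, 4)
  expect_error(dw_statistic(c(0, 0, 0)), "zero")
  expect_error(dw_statistic(c(1, 2)), "at least 3")

  set.seed(21)
  for (i in 1:5) {
    e <- rnorm(15)
    A <- dw_matrix_A(15)
    expect_equal(dw_statistic(e)$d, as.numeric(t(e) %*% A %*% e / sum(e^2)),
      tolerance = 1e-12
    )
  }
})

test_that("d is invariant to affine reparameterization of design columns", {
  set.seed(22)
  t <- 1:30
  y <- rnorm(30)
  X1 <- poly_design(t, 2)
  # same column space, different parameterization
  M <- cbind(10 + 2 * t, (t - 3)^2 + t)
  X2 <- as_design(M)
  d1 <- dw_statistic(residuals(fit_ols(X1, y)))$d
  d2 <- dw_statistic(residuals(fit_ols(X2, y)))$d
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("null moments match Monte Carlo and the large-N limits", {
  # 150-year linear design
  m150 <- dw_moments(poly_design(1850:1999, 1))
  expect_equal(round(m150$E_d, 2), 2.01)

  # large-N limit: E(d) -> 2, V(d) -> 4/N (banded computation, no dense A)
  n <- 100000
  mb <- dw_moments(poly_design(seq_len(n), 1))
  expect_equal(mb$E_d, 2, tolerance = 1e-3)
  expect_equal(mb$V_d, 4 / n, tolerance = 1e-3)

  # white-noise Monte Carlo oracle at N = 20
  set.seed(23)
  n <- 20
  X <- poly_design(seq_len(n), 1)
  qrX <- qr(unclass(X))
  ds <- replicate(20000, {
    e <- qr.resid(qrX, rnorm(n))
    sum(diff(e)^2) / sum(e^2)
  })
  m <- dw_moments(X)
  se_mean <- sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - m$E_d), 3 * se_mean)
  # variance of a sample variance ~ 2 V^2 / n for near-normal d
  se_var <- sqrt(2 / length(ds)) * var(ds)
  expect_lt(abs(var(ds) - m$V_d), 3 * se_var + 0.02 * m$V_d)
})

test_that("beta test reproduces its structural identities", {
  m <- dw_moments(poly_design(1:40, 1))
  r <- dw_beta_test(m$E_d, m$E_d, m$V_d)
  # 2*min(F, 1-F) equals 1 exactly at the beta median; at the mean E(d) it
  # is marginally below (the matched beta is very slightly skewed)
  expect_gt(r$p_two_tailed, 0.99)
  expect_lt(r$ci_low, m$E_d)
  expect_gt(r$ci_high, m$E_d)
  expect_equal(r$beta_a + r$beta_b, m$E_d * (4 - m$E_d) / m$V_d)
  expect_error(dw_beta_test(1, 5, 0.1), "E_d")
  expect_error(dw_beta_test(1, 2, -1), "V_d")
})

test_that("transformed-residual test with identity model equals the OLS test", {
  set.seed(24)
  X <- poly_design(1:30, 1)
  y <- simulate_ar1(30, 0.3)
  f_id <- fit_gls(X, y, cor_identity(30))
  f_ols <- fit_ols(X, y)
  r1 <- dw_test(f_id)
  r0 <- dw_test(f_ols)
  expect_equal(r1$d, r0$d)
  expect_equal(r1$E_d, r0$E_d)
  expect_equal(r1$p_two_tailed, r0$p_two_tailed)
  # identity-model GLS moments equal OLS moments exactly
  expect_identical(dw_moments(X, cor_identity(30)), dw_moments(X))
})

test_that("d statistic agrees with an established implementation on OLS residuals", {
  skip_if_not_installed("lmtest")
  set.seed(25)
  t <- 1:35
  y <- simulate_ar1(35, 0.5) + 0.05 * t
  lmfit <- stats::lm(y ~ t)
  d_ref <- unname(lmtest::dwtest(lmfit)$statistic)
  d_ours <- dw_statistic(residuals(fit_ols(poly_design(t, 1), y)))$d
  expect_equal(d_ours, d_ref, tolerance = 1e-10)
})

test_that("null rejection rate of the two-tailed 95% beta test is 5% +/- 1%", {
  set.seed(26)
  n <- 40
  X <- poly_design(seq_len(n), 1)
  m <- dw_moments(X)
  ab <- m$E_d * (4 - m$E_d) / m$V_d
  a <- ab * m$E_d / 4
  b <- ab - a
  qrX <- qr(unclass(X))
  ci <- 4 * qbeta(c(0.025, 0.975), a, b)
  rej <- replicate(10000, {
    e <- qr.resid(qrX, rnorm(n))
    d <- sum(diff(e)^2) / sum(e^2)
    d < ci[1] || d > ci[2]
  })
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("GLS transformed-residual test passes at the true rho in most trials", {
  set.seed(27)
  n <- 200
  X <- poly_design(seq_len(n), 1)
  model <- cor_ar1(0.6, n)
  P <- principal_sqrt_inv(model)
  m <- dw_moments(X, model, P = P)
  # the composed fast path equals dw_test on one dataset
  y0 <- simulate_ar1(n, 0.6)
  f0 <- fit_gls(X, y0, model)
  r_full <- dw_test(f0)
  d_fast <- dw_statistic(as.numeric(P %*% residuals(f0)))$d
  expect_equal(r_full$d, d_fast, tolerance = 1e-12)
  expect_equal(r_full$E_d, m$E_d, tolerance = 1e-12)

  ci <- with(
    list(ab = m$E_d * (4 - m$E_d) / m$V_d),
    4 * qbeta(c(0.025, 0.975), ab * m$E_d / 4, ab * (1 - m$E_d / 4))
  )
  pass <- replicate(1000, {
    y <- simulate_ar1(n, 0.6)
    f <- fit_gls(X, y, model)
    d <- dw_statistic(as.numeric(P %*% residuals(f)))$d
    d >= ci[1] && d <= ci[2]
  })
  expect_gte(mean(pass), 0.93)
})
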