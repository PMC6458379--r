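test_that("ACF and DW point estimators match hand values and clamp policy", {
  expect_equal(rho_acf(c(1, 0, -1, 0))$rho, 0)
  expect_equal(rho_acf(c(1, 1, -1, -1))$rho, 0.25)
  expect_error(rho_acf(c(0, 0, 0)), "zero")

  expect_equal(rho_dw(2)$rho, 0)
  expect_equal(rho_dw(0.850)$rho, 0.575)
  expect_warning(r0c <- rho_dw(0), "clamped")
  expect_equal(r0c$rho, 0.9999)
  expect_error(rho_dw(4.5), "0, 4")

  # consistency on a long AR(1) series
  set.seed(31)
  e <- simulate_ar1(1e5, 0.8)
  e <- e - mean(e)
  expect_equal(rho_acf(e)$rho, 0.8, tolerance = 0.015)
})

test_that("iterated ML is consistent and lands on the conditional-likelihood optimum", {
  # null consistency on long white noise
  set.seed(32)
  n <- 1e5
  X <- poly_design(seq_len(n), 1)
  est <- rho_ml_iterated(X, rnorm(n))
  expect_true(est$converged)
  expect_lt(abs(est$rho), 0.01)

  # grid-search oracle at N = 30: the conditional likelihood is flat near
  # its optimum, so individual datasets may differ a little; the iterate
  # must agree closely on average and never lose a meaningful amount of
  # likelihood
  set.seed(33)
  diffs <- ll_gaps <- numeric(6)
  for (i in 1:6) {
    y <- simulate_ar1(30, 0.5) + 0.1 * (1:30)
    X30 <- poly_design(1:30, 1)
    it <- rho_ml_iterated(X30, y)$rho
    gr <- grid_ml_oracle(X30, y)
    diffs[i] <- abs(it - gr)
    ll_gaps[i] <- cond_ll(gr, design = X30, y = y) - cond_ll(it, design = X30, y = y)
  }
  expect_lt(mean(diffs), 0.01)
  expect_lt(max(diffs), 0.05)
  expect_lt(max(ll_gaps), 0.05)
})

test_that("TADW is zero at d = E(d), asymptotically 1 - d/2, and less biased than ML", {
  n <- 40
  X <- poly_design(seq_len(n), 1)
  m <- dw_moments(X)
  expect_equal(rho_tadw(m$E_d, m$E_d, m$V_d, n, 1)$rho, 0)

  # asymptotic limit
  nb <- 1e5
  mb <- dw_moments(poly_design(seq_len(nb), 1))
  for (d in c(0.4, 1.2, 2.0, 2.8)) {
    expect_lt(abs(rho_tadw(d, mb$E_d, mb$V_d, nb, 1)$rho - (1 - d / 2)), 0.01)
  }

  expect_error(rho_tadw(1.5, 2, 0.1, 5, 1), "n - k - 4")

  # Monte Carlo bias ordering at rho = 0.9, N = 100 (smaller block than the
  # acceptance run; same design)
  set.seed(34)
  n <- 100
  X <- poly_design(seq_len(n), 1)
  m <- dw_moments(X)
  qrX <- qr(unclass(X))
  r_t <- r_m <- numeric(300)
  for (i in seq_along(r_t)) {
    y <- simulate_ar1(n, 0.9)
    e <- qr.resid(qrX, y)
    d <- sum(diff(e)^2) / sum(e^2)
    r_t[i] <- rho_tadw(d, m$E_d, m$V_d, n, 1)$rho
    r_m[i] <- rho_ml_iterated(X, y)$rho
  }
  expect_lt(abs(mean(r_t) - 0.9), abs(mean(r_m) - 0.9))
})

test_that("TADW and DW estimates converge to each other at large N", {
  set.seed(35)
  n <- 1e5
  X <- poly_design(seq_len(n), 1)
  y <- simulate_ar1(n, 0.6)
  e <- qr.resid(qr(unclass(X)), y)
  d <- sum(diff(e)^2) / sum(e^2)
  m <- dw_moments(X)
  expect_lt(abs(rho_tadw(d, m$E_d, m$V_d, n, 1)$rho - rho_dw(d)$rho), 0.005)
})

test_that("all estimators are near zero on long white-noise residuals", {
  set.seed(36)
  n <- 20000
  X <- poly_design(seq_len(n), 1)
  y <- rnorm(n)
  f <- fit_ols(X, y)
  e <- residuals(f)
  d <- dw_statistic(e)$d
  m <- dw_moments(X)
  expect_lt(abs(rho_acf(e)$rho), 0.02)
  expect_lt(abs(rho_dw(d)$rho), 0.02)
  expect_lt(abs(rho_tadw(d, m$E_d, m$V_d, n, 1)$rho), 0.02)
  expect_lt(abs(rho_ml_iterated(X, y)$rho), 0.02)
})

test_that("rho_max, effective_n and scaled_se follow their formulas", {
  expect_equal(rho_max(100), 0.8)
  expect_gt(rho_max(200), rho_max(100))
  expect_equal(rho_max(40), 0.8 * 0.4^0.07)

  expect_equal(effective_n(50, 0), 50)
  expect_equal(effective_n(38, 0.9), 2)
  expect_equal(effective_n(100, -0.5), 300)

  expect_equal(scaled_se(1.3, 0), 1.3)
  expect_equal(scaled_se(2, 0.9), 2 * sqrt(19))
  expect_error(scaled_se(-1, 0.5), "positive")

  # scaled SE approximates the known-rho GLS slope SE at large N
  set.seed(37)
  n <- 500
  X <- poly_design(seq_len(n), 1)
  rat <- replicate(30, {
    y <- simulate_ar1(n, 0.7)
    se_g <- fit_gls(X, y, cor_ar1(0.7, n))$se[2]
    se_s <- scaled_se(fit_ols(X, y)$se[2], 0.7)
    se_s / se_g
  })
  expect_lt(abs(mean(rat) - 1), 0.15)
})

test_that("extrapolation combines the two fits per coefficient and gates admissibility", {
  set.seed(38)
  n <- 60
  X <- poly_design(seq_len(n), 1)
  y <- simulate_ar1(n, 0.5)
  f1 <- fit_gls(X, y, cor_ar1(0.4, n))
  f2 <- fit_gls(X, y, cor_ar1(0.5, n))
  ex <- extrapolate(f1, f2)
  expect_equal(ex$t_extrap, 2 * ex$t_tadw - ex$t_dw)
  # degenerate extrapolation: same fit twice
  ex0 <- extrapolate(f2, f2)
  expect_equal(ex0$t_extrap, ex0$t_dw)
  # mismatched designs fail
  expect_error(
    extrapolate(f1, fit_gls(poly_design(seq_len(n), 2), y, cor_ar1(0.5, n))),
    "same design"
  )
  # rho above the admissibility bound flags the result
  f3 <- fit_gls(X, y, cor_ar1(0.99, n))
  ex_bad <- extrapolate(f1, f3)
  expect_false(attr(ex_bad, "admissible"))
})
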