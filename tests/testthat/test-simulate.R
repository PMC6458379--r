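test_that("AR(1) generator has the stationary moments and matches the loop oracle", {
  set.seed(71)
  e <- simulate_ar1(1e5, 0.8)
  expect_equal(var(e), 1 / (1 - 0.8^2), tolerance = 0.03)
  n <- length(e)
  r1 <- sum((e[-n] - mean(e)) * (e[-1] - mean(e))) / sum((e - mean(e))^2)
  expect_equal(r1, 0.8, tolerance = 0.01)

  # rho = 0 degenerates to iid standard normal
  set.seed(72)
  z <- simulate_ar1(1e5, 0)
  expect_gt(stats::ks.test(z, pnorm)$p.value, 0.01)

  # identical to the explicit-loop oracle under the same RNG stream
  set.seed(73)
  a <- simulate_ar1(500, 0.6)
  set.seed(73)
  b <- ar1_loop(500, 0.6)
  expect_equal(a, b, tolerance = 1e-12)

  # seeded determinism
  expect_identical(simulate_ar1(50, 0.5, seed = 9), simulate_ar1(50, 0.5, seed = 9))
})

test_that("spatial field generator realizes the requested covariance", {
  set.seed(74)
  coords <- matrix(runif(100, -50, 50), 50, 2)
  S <- exponential_correlation(coords, r0 = 20)
  sqS <- spatial_sqrt_S(coords, r0 = 20)
  expect_equal(sqS %*% sqS, S, tolerance = 1e-10)

  # empirical covariance over replicates matches S within 3 MC SEs
  reps <- 20000
  Z <- matrix(rnorm(50 * reps), 50, reps)
  fields <- sqS %*% Z
  emp <- tcrossprod(fields) / reps
  # sampling SE of a covariance entry ~ sqrt((1 + s_ij^2)/reps)
  se <- sqrt((1 + S^2) / reps)
  expect_lt(max(abs(emp - S) / se), 5)
  expect_lt(mean(abs(emp - S) > 3 * se), 0.01)

  # r0 -> 0 limit: effectively independent samples
  set.seed(75)
  f_small <- simulate_spatial_field(coords, r0 = 1e-6)
  S_small <- exponential_correlation(coords, r0 = 1e-6)
  expect_lt(max(abs(S_small[upper.tri(S_small)])), 0.05)
  expect_equal(length(f_small), 50)
})

test_that("1-D unit-grid spatial fields match the AR(1) generator statistically", {
  set.seed(76)
  n <- 400
  grid <- matrix(seq_len(n), ncol = 1)
  sqS <- spatial_sqrt_S(grid, r0 = -1 / log(0.75))
  r1 <- function(x) {
    m <- length(x)
    sum((x[-m] - mean(x)) * (x[-1] - mean(x))) / sum((x - mean(x))^2)
  }
  lag_sp <- replicate(60, r1(as.numeric(sqS %*% rnorm(n))))
  lag_ar <- replicate(60, r1(simulate_ar1(n, 0.75)))
  expect_gt(stats::t.test(lag_sp, lag_ar)$p.value, 0.01)
  expect_gt(stats::var.test(lag_sp, lag_ar)$p.value, 0.01)
})

test_that("harnesses return tidy per-trial tables and degenerate cases work", {
  out <- mc_null_calibration(trials = 3, n = 30, rho = 0.5, estimators = c("known", "dw"), seed = 77)
  expect_identical(nrow(out), 6L)
  expect_setequal(unique(out$estimator), c("known", "dw"))
  expect_true(all(is.finite(out$t)))

  # single-trial spatial smoke
  out_sp <- mc_null_calibration(trials = 1, n = 20, r0 = 10, dim = 2, seed = 78)
  expect_identical(nrow(out_sp), 5L)

  bias <- mc_bias_study(trials = 20, n = 25, rho = 0.6, estimators = "dw", seed = 79)
  expect_identical(names(bias), c("n", "estimator", "mean", "lo", "hi"))
  expect_identical(bias$estimator, "dw")
  expect_true(bias$lo <= bias$mean && bias$mean <= bias$hi)

  # zero slope range reduces the sweep to a null calibration
  sw <- mc_detection_sweep(trials = 8, n = 40, rho = 0.5, slope_range = c(0, 0), seed = 80)
  expect_true(all(sw$slope == 0))
  exc <- sweep_exceedance(sw)
  expect_true(all(exc$fraction >= 0 & exc$fraction <= 1))

  # determinism: same seed, same table
  s1 <- mc_detection_sweep(trials = 5, n = 30, seed = 81)
  s2 <- mc_detection_sweep(trials = 5, n = 30, seed = 81)
  expect_identical(s1, s2)
})

test_that("known-correlation GLS slope t is t-distributed (large-N reference)", {
  set.seed(82)
  n <- 400
  X <- poly_design(seq_len(n), 1)
  m <- dw_moments(X)
  ts <- replicate(1000, {
    y <- simulate_ar1(n, 0.85)
    fit_gls(X, y, cor_ar1(0.85, n))$t[2]
  })
  expect_gt(stats::ks.test(ts, pt, df = n - 2)$p.value, 0.01)
})
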