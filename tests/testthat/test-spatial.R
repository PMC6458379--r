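test_that("the path on equally spaced 1-D points is monotone with r_bar = spacing", {
  p <- nnn_path(matrix(seq(0, 18, by = 2), ncol = 1))
  expect_true(all(diff(p$order) == 1) || all(diff(p$order) == -1))
  expect_equal(p$r_bar, 2)
  expect_equal(p$m_coloc, 0L)
  expect_true(all(abs(rowSums(p$R) - 1) < 1e-12))
})

test_that("the greedy walk matches an independent brute-force oracle", {
  set.seed(51)
  for (i in 1:5) {
    coords <- matrix(runif(20), 10, 2)
    p <- nnn_path(coords)
    # p$order indexes merged locations; with no duplicates they are the rows
    expect_equal(p$m_coloc, 0L)
    expect_equal(unname(unlist(p$merge_map)), unname(greedy_walk(coords)))
  }
})

test_that("duplicate locations merge into a mean-valued node", {
  coords <- rbind(c(0, 0), c(5, 0), c(5, 0), c(9, 0))
  p <- nnn_path(coords)
  expect_equal(p$m_coloc, 1L)
  expect_equal(nrow(p$R), 3L)
  merged_row <- p$R[vapply(p$merge_map, length, 1L) == 2L, ]
  expect_equal(sort(merged_row[merged_row > 0]), c(0.5, 0.5))
  # reduction conserves group means
  e <- c(1, 2, 4, 8)
  er <- as.numeric(p$R %*% e)
  expect_true(3 %in% er) # mean of the duplicated pair
  expect_error(nnn_path(matrix(0, 4, 2)), "co-located")
})

test_that("spatial d reproduces the time-series statistic on a 1-D grid", {
  set.seed(52)
  n <- 40
  t <- seq_len(n)
  y <- simulate_ar1(n, 0.5) + 0.1 * t
  X <- poly_design(t, 1)
  e <- residuals(fit_ols(X, y))
  p <- nnn_path(matrix(t, ncol = 1))
  sd1 <- spatial_dw(e, p)
  expect_equal(sd1$d, dw_statistic(e)$d, tolerance = 1e-12)

  # hand value on path-ordered residuals
  p4 <- nnn_path(matrix(1:4, ncol = 1))
  expect_equal(spatial_dw(c(1, -1, 1, -1), p4)$d, 3)
  expect_equal(spatial_dw(rep(2, 4), p4)$ssrfd, 0)
})

test_that("the full spatial stack reproduces the time-series stack on 1-D grids", {
  set.seed(53)
  n <- 60
  t <- seq_len(n)
  y <- simulate_ar1(n, 0.6) + 0.05 * t
  X <- poly_design(t, 1)
  f <- fit_ols(X, y)
  p <- nnn_path(matrix(t, ncol = 1))
  est <- estimate_r0(residuals(f), p, X, method = "tadw")
  # same rho as the time-series TADW
  m <- dw_moments(X)
  d <- dw_statistic(residuals(f))$d
  rho_ts <- rho_tadw(d, m$E_d, m$V_d, n, 1)$rho
  expect_equal(est$rho, rho_ts, tolerance = 1e-10)
  expect_equal(est$r0, -1 / log(rho_ts), tolerance = 1e-10)

  # and the resulting exponential GLS equals the AR(1) GLS
  f_sp <- fit_gls(X, y, cor_exponential(matrix(t, ncol = 1), r0 = est$r0))
  f_ts <- fit_gls(X, y, cor_ar1(rho_ts, n))
  expect_equal(coef(f_sp), coef(f_ts), tolerance = 1e-8)
  expect_equal(f_sp$se, f_ts$se, tolerance = 1e-8)
})

test_that("r0 estimation inverts the mean-spacing relation and flags non-positive rho", {
  # rho = exp(-1), r_bar = 1  ->  r0 = 1
  p <- nnn_path(matrix(1:10, ncol = 1))
  expect_equal(-p$r_bar / log(exp(-1)), 1)
  # negative-correlation residuals give the fallback signal
  e_alt <- rep(c(1, -1), 10)
  X <- poly_design(1:20, 1)
  p20 <- nnn_path(matrix(1:20, ncol = 1))
  est <- estimate_r0(e_alt, p20, X, method = "dw")
  expect_false(est$positive)
  expect_true(is.na(est$r0))
})

test_that("semivariogram cloud, class means and exponential fit behave", {
  expect_equal(semivariogram_cloud(c(0, 1), matrix(c(0, 1), ncol = 1))$gamma, 0.5)
  expect_equal(semivariogram_cloud(rep(1, 5), matrix(1:5, ncol = 1))$gamma, rep(0, 10))

  # class means track the AR(1) asymptote sigma_e^2 (1 - rho^m) for small m.
  # unit-width classes on a unit grid make class m hold exactly the lag-m
  # pairs (mid = m - 0.5)
  set.seed(54)
  n <- 1001
  rho <- 0.7
  e <- simulate_ar1(n, rho)
  e <- e - mean(e)
  sigma2 <- sum(e^2) / (n - 1)
  sv <- semivariogram(e, matrix(seq_len(n), ncol = 1),
    n_classes = 500, sill = sigma2
  )
  cls <- sv$classes
  for (m in 1:5) {
    got <- cls$gamma_mean[abs(cls$mid - (m - 0.5)) < 1e-6]
    expect_equal(got, sigma2 * (1 - rho^m), tolerance = 0.10 * sigma2)
  }
  # the mid-distance abscissa convention shifts each class by half a lag on
  # this unit-grid data, biasing the fitted range low; assert the right
  # scale rather than lag-exact recovery
  expect_gt(sv$r0_hat, -1 / log(rho) / 2)
  expect_lt(sv$r0_hat, -1 / log(rho) * 2)
})

test_that("co-location kd follows its closed form and clamps", {
  e <- c(1, 1, 2, 2, 5, 5)
  pairs <- cbind(c(1, 3, 5), c(2, 4, 6))
  expect_equal(colocated_kd(e, pairs, sigma2_e = 1), 0)
  # sum of squared differences = m * sigma2 -> kd = log 2
  e2 <- c(0, 1, 0, 1, 0, 1) # each pair differs by 1, so the sum is m = 3
  expect_equal(colocated_kd(e2, pairs, sigma2_e = 1), log(2))
  expect_warning(kd <- colocated_kd(e2, pairs, sigma2_e = 0.5), "uncorrelated")
  expect_gt(kd, 10)
})

test_that("spatial GLS validity test matches the time-series test on a grid", {
  set.seed(55)
  n <- 50
  t <- seq_len(n)
  y <- simulate_ar1(n, 0.6)
  X <- poly_design(t, 1)
  rho <- 0.6
  f_ts <- fit_gls(X, y, cor_ar1(rho, n))
  r_ts <- dw_test(f_ts)
  p <- nnn_path(matrix(t, ncol = 1))
  f_sp <- fit_gls(X, y, cor_exponential(matrix(t, ncol = 1), r0 = -1 / log(rho)))
  r_sp <- spatial_dw_test_gls(f_sp, p, X)
  expect_equal(r_sp$d, r_ts$d, tolerance = 1e-8)
  expect_equal(r_sp$E_d, r_ts$E_d, tolerance = 1e-8)
  expect_equal(r_sp$p_two_tailed, r_ts$p_two_tailed, tolerance = 1e-6)
})
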