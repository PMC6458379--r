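new_rho_estimate <- function(method, rho, iterations = NA_integer_, converged = NA) {
  structure(
    list(method = method, rho = rho, iterations = iterations, converged = converged),
    class = "rho_estimate"
  )
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat(sprintf("<rho_estimate: %s> rho = %.4f", x$method, x$rho))
  if (!is.na(x$iterations)) cat(sprintf(" (%d iterations, %s)", x$iterations, if (isTRUE(x$converged)) "converged" else "NOT converged"))
  cat("\n")
  invisible(x)
}

#' @export
tidy.rho_estimate <- function(x, ...) {
  tibble(method = x$method, rho = x$rho, iterations = x$iterations, converged = x$converged)
}

#' Lag-1 autocorrelation estimate of rho
#'
#' `sum(e_i e_{i+1}) / sum(e_i^2)` on OLS residuals (whose mean is zero).
#'
#' @param e Residual vector, length >= 3.
#' @return A `"rho_estimate"`.
#' @export
rho_acf <- function(e) {
  e <- as.numeric(e)
  if (length(e) < 3L) abort("need at least 3 residuals.")
  den <- sum(e^2)
  if (den == 0) abort("all residuals are zero.")
  n <- length(e)
  new_rho_estimate("acf", clamp_rho(sum(e[-n] * e[-1L]) / den, warn = FALSE))
}

#' Durbin-Watson estimate of rho
#'
#' `rho = 1 - d/2`, clamped into (-1, 1).
#'
#' @param d Durbin-Watson statistic in `[0, 4]`.
#' @return A `"rho_estimate"`.
#' @export
rho_dw <- function(d) {
  if (d < 0 || d > 4) abort("`d` must lie in [0, 4].")
  new_rho_estimate("dw", clamp_rho(1 - d / 2, what = "rho (1 - d/2)"))
}

# O(n) Prais-Winsten whitened OLS; returns coefficients only (used by the
# ML iteration, where neither SEs nor the S-scale residual SE are needed).
pw_coef <- function(X, y, rho) {
  n <- length(y)
  Ty <- c(sqrt(1 - rho^2) * y[1L], y[-1L] - rho * y[-n])
  TX <- rbind(sqrt(1 - rho^2) * X[1L, ], X[-1L, , drop = FALSE] - rho * X[-n, , drop = FALSE])
  qr.coef(qr(TX), Ty)
}

# Conditional (on e1) ML update for rho from a residual vector.
ml_rho_update <- function(e) {
  n <- length(e)
  lead <- e[-1L]
  lag <- e[-n]
  num <- sum((lead - mean(lead)) * (lag - mean(lag)))
  den <- sum((lag - mean(lag))^2)
  num / den
}

#' Iterated joint maximum-likelihood estimate of rho
#'
#' Alternates (a) the conditional-on-first-observation ML update of `rho`
#' from the current residuals with (b) a GLS refit of the regression under
#' AR1(rho), until the change in `rho` falls below `tol`. Starts from the
#' lag-1 autocorrelation of the OLS residuals. Valid for equally spaced
#' one-dimensional data only.
#'
#' @inheritParams fit_ols
#' @param tol Convergence tolerance on `rho` (default `1e-6`).
#' @param max_iter Iteration cap (default 100). On non-convergence the last
#'   iterate is returned with `converged = FALSE`.
#' @return A `"rho_estimate"` with `iterations` and `converged`.
#' @export
rho_ml_iterated <- function(X, y, tol = 1e-6, max_iter = 100L) {
  y <- as.numeric(y)
  X0 <- unclass(X)
  e <- qr.resid(qr(X0), y)
  n <- length(y)
  rho <- clamp_rho(sum(e[-n] * e[-1L]) / sum(e^2), warn = FALSE)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    b <- pw_coef(X0, y, rho)
    e <- y - as.numeric(X0 %*% b)
    rho_new <- clamp_rho(ml_rho_update(e), warn = FALSE)
    if (abs(rho_new - rho) < tol) {
      rho <- rho_new
      converged <- TRUE
      break
    }
    rho <- rho_new
  }
  if (!converged) warn(sprintf("ML iteration did not converge in %d iterations; returning last iterate.", max_iter))
  new_rho_estimate("ml", rho, iterations = it, converged = converged)
}

#' Tanh-adjusted Durbin-Watson (TADW) estimate of rho
#'
#' A bias-reduced estimate for small, highly correlated samples. The raw
#' `1 - d/2` is recentred by the exact null expectation and rescaled on the
#' arctanh scale:
#' \deqn{\hat\rho = \tanh\left(\left[\mathrm{artanh}(1 - d/2) -
#'   \mathrm{artanh}(1 - E(d)/2)\right] \cdot c\right),\quad
#'   c = \frac{2\,(N - k + 2)}{(N - k - 4)\sqrt{N\,V(d)}}.}
#' The scale factor satisfies: the estimate is exactly 0 when `d = E(d)`;
#' `c -> 1` as `N -> infinity` (since `E(d) -> 2`, `V(d) -> 4/N`), so the
#' estimate converges to `1 - d/2`; and at small `N` it expands the unduly
#' compressed spread of `d`, which Monte Carlo testing shows reduces the
#' downward bias at large positive rho below that of iterated ML. The
#' arctanh arguments are clamped into (-1, 1); any stray imaginary residue
#' of the transform is discarded by construction.
#'
#' @param d Durbin-Watson statistic of the OLS residuals.
#' @param E_d,V_d Exact OLS null moments from [dw_moments()].
#' @param n Number of observations.
#' @param k Number of non-intercept parameters; requires `n - k - 4 > 0`.
#' @return A `"rho_estimate"`.
#' @export
rho_tadw <- function(d, E_d, V_d, n, k) {
  if (n - k - 4 <= 0) abort("TADW requires n - k - 4 > 0.")
  if (d <= 0 || d >= 4) {
    warn("d at the boundary of [0, 4]; clamping.")
  }
  z <- atanh(clamp_rho(1 - d / 2, warn = FALSE)) - atanh(clamp_rho(1 - E_d / 2, warn = FALSE))
  cc <- 2 * (n - k + 2) / ((n - k - 4) * sqrt(n * V_d))
  new_rho_estimate("tadw", clamp_rho(tanh(z * cc), warn = FALSE))
}

#' Admissibility bound for extrapolated inference
#'
#' `rho_max = 0.8 (N / 100)^0.07`. Extrapolated t-values are calibrated
#' between the 2.5% and 97.5% points of the t-distribution only while the
#' correlation does not exceed this bound.
#'
#' @param n Number of observations.
#' @return The bound.
#' @export
rho_max <- function(n) {
  if (any(n < 1)) abort("`n` must be >= 1.")
  0.8 * (n / 100)^0.07
}

#' Effective number of samples under AR(1) correlation
#'
#' `N_eff = N (1 - rho) / (1 + rho)`. With small, highly correlated samples
#' this can fall to a handful of effective observations (e.g. N = 38,
#' rho = 0.9 gives 2), wiping out the degrees of freedom.
#'
#' @param n Number of observations.
#' @param rho AR(1) correlation in (-1, 1).
#' @return Effective sample size.
#' @export
effective_n <- function(n, rho) {
  check_rho(rho)
  n * (1 - rho) / (1 + rho)
}

#' Scaled OLS standard error under AR(1) correlation
#'
#' Applies the square root of the effective-sample-size scaling directly to
#' an OLS coefficient standard error: `se * sqrt((1 + rho)/(1 - rho))`. A
#' quick approximation to the GLS known-rho standard error for large `N`
#' that avoids the zero-degrees-of-freedom failure of `N_eff` itself.
#'
#' @param se_ols OLS coefficient standard error (> 0).
#' @param rho AR(1) correlation in (-1, 1).
#' @return Scaled standard error.
#' @export
scaled_se <- function(se_ols, rho) {
  check_rho(rho)
  if (any(se_ols <= 0)) abort("`se_ols` must be positive.")
  se_ols * sqrt((1 + rho) / (1 - rho))
}

#' Estimate rho by every available method
#'
#' Convenience wrapper running the ACF lag-1, Durbin-Watson, iterated ML and
#' TADW estimators on an OLS fit of equally spaced data.
#'
#' @param fit An OLS `"trend_fit"`.
#' @param methods Which estimators to run.
#' @return A tibble with one row per estimator.
#' @export
estimate_rho <- function(fit, methods = c("acf", "dw", "ml", "tadw")) {
  if (!inherits(fit, "trend_fit")) abort("`fit` must be a trend_fit.")
  methods <- match.arg(methods, c("acf", "dw", "ml", "tadw"), several.ok = TRUE)
  e <- fit$residuals
  d <- dw_statistic(e)$d
  m <- if (any(methods == "tadw")) dw_moments(fit$X) else NULL
  ests <- purrr::map(methods, function(mm) {
    switch(mm,
      acf = rho_acf(e),
      dw = rho_dw(d),
      ml = rho_ml_iterated(fit$X, fit$y),
      tadw = rho_tadw(d, m$E_d, m$V_d, fit$n, fit$k)
    )
  })
  purrr::map_dfr(ests, tidy)
}
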