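#' Durbin-Watson statistic of a residual vector
#'
#' `d = SSRFD / SSR`, the sum of squared residual forward differences over
#' the sum of squared residuals. Values near 2 indicate uncorrelated
#' residuals; `d -> 0` under strong positive serial correlation.
#'
#' @param e Residual vector, length `>= 3`, not all zero.
#' @return A list with `d`, `ssrfd` and `ssr`.
#' @export
dw_statistic <- function(e) {
  e <- as.numeric(e)
  if (length(e) < 3L) abort("need at least 3 residuals.")
  ssr <- sum(e^2)
  if (ssr == 0) abort("all residuals are zero; d is undefined.")
  ssrfd <- sum(diff(e)^2)
  list(d = ssrfd / ssr, ssrfd = ssrfd, ssr = ssr)
}

#' Tridiagonal forward-difference matrix A
#'
#' The symmetric matrix for which `SSRFD = e' A e`: diagonal
#' `(1, 2, ..., 2, 1)` and -1 on the sub/superdiagonals.
#'
#' @param n Dimension.
#' @return An `n x n` matrix.
#' @export
dw_matrix_A <- function(n) {
  A <- diag(c(1, rep(2, n - 2L), 1))
  idx <- seq_len(n - 1L)
  A[cbind(idx, idx + 1L)] <- -1
  A[cbind(idx + 1L, idx)] <- -1
  A
}

# A %*% X without forming A: rows are second differences with free ends.
a_times <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  out <- 2 * X
  out[1L, ] <- X[1L, ] - X[2L, ]
  out[n, ] <- X[n, ] - X[n - 1L, ]
  if (n > 2L) {
    mid <- 2:(n - 1L)
    out[mid, ] <- 2 * X[mid, , drop = FALSE] - X[mid - 1L, , drop = FALSE] - X[mid + 1L, , drop = FALSE]
  }
  out
}

#' Exact null moments of the Durbin-Watson statistic
#'
#' Expected value and variance of `d` under the null hypothesis of
#' uncorrelated errors, for a given design. With
#' `p = tr(A) - tr[X'AX (X'X)^-1]` and
#' `q = tr(A^2) - 2 tr[X'A^2X (X'X)^-1] + tr[(X'AX (X'X)^-1)^2]`,
#' `E(d) = p / (N - k - 1)` and
#' `V(d) = 2 (q - p E(d)) / ((N - k - 1)(N - k + 1))`.
#' When a non-identity correlation `model` is supplied the moments refer to
#' the transformed-residual statistic of a GLS fit: `X` is replaced by `P X`
#' (with `P` the symmetric principal root of `S^-1`) and `(X'X)^-1` by
#' `(X' S^-1 X)^-1`. Traces are evaluated with banded products, never a
#' dense `A`.
#'
#' @param X Design matrix.
#' @param model Optional [cor_model] for the GLS (transformed-residual)
#'   context; `NULL` or an identity model gives the OLS moments.
#' @param P Optional pre-computed [principal_sqrt_inv()] of `model`, to
#'   avoid repeating the eigendecomposition.
#' @return A list with `E_d`, `V_d`, `p`, `q`.
#' @export
dw_moments <- function(X, model = NULL, P = NULL) {
  k <- design_k(X)
  Xw <- unclass(X)
  if (!is.null(model) && inherits(model, "cor_model") && model$kind != "identity") {
    if (is.null(P)) P <- principal_sqrt_inv(model)
    Xw <- P %*% Xw
  }
  n <- nrow(Xw)
  if (n - k + 1L <= 0L) abort("design too small for the variance formula.")
  XtXinv <- chol2inv(qr.R(qr(Xw)))
  AX <- a_times(Xw)
  XAX <- crossprod(Xw, AX)
  B <- XAX %*% XtXinv # X'AX (X'X)^-1
  XA2X <- crossprod(AX) # X'A^2X, since A is symmetric
  p <- (2 * n - 2) - sum(diag(B))
  q <- (6 * n - 8) - 2 * sum(diag(XA2X %*% XtXinv)) + sum(B * t(B))
  E_d <- p / (n - k - 1)
  V_d <- 2 * (q - p * E_d) / ((n - k - 1) * (n - k + 1))
  if (!is.finite(V_d) || V_d <= 0) abort("null variance of d is not positive; design is degenerate.")
  list(E_d = E_d, V_d = V_d, p = p, q = q)
}

#' Beta-approximation significance test for the Durbin-Watson statistic
#'
#' `d / 4` is approximated as Beta(a, b) with moments matched to the exact
#' null mean and variance: `a + b = E(d)(4 - E(d))/V(d)` and
#' `a = (a + b) E(d)/4`. The two-tailed probability is
#' `2 min(F(d/4), 1 - F(d/4))` with `F` the regularized incomplete beta, and
#' the confidence interval for `d` comes from the beta quantiles scaled
#' by 4.
#'
#' @param d Observed Durbin-Watson statistic.
#' @param E_d,V_d Null moments from [dw_moments()].
#' @param alpha Two-sided test level (default 0.05).
#' @param context Label recorded in the report: `"ols"` or
#'   `"gls_transformed"`.
#' @return A `"dw_report"` list: `d`, `E_d`, `V_d`, `beta_a`, `beta_b`,
#'   `p_two_tailed`, `ci_low`, `ci_high`, `verdict` (`"pass"` if `d` lies
#'   inside the interval), `context`.
#' @export
dw_beta_test <- function(d, E_d, V_d, alpha = 0.05, context = "ols") {
  if (E_d <= 0 || E_d >= 4) abort("`E_d` must lie in (0, 4).")
  if (V_d <= 0) abort("`V_d` must be positive.")
  ab <- E_d * (4 - E_d) / V_d
  a <- ab * E_d / 4
  b <- ab - a
  if (a <= 0 || b <= 0) abort("implied beta shape parameters are not positive.")
  lower <- pbeta(d / 4, a, b)
  p <- 2 * min(lower, 1 - lower)
  ci <- 4 * qbeta(c(alpha / 2, 1 - alpha / 2), a, b)
  structure(
    list(
      d = d, E_d = E_d, V_d = V_d, beta_a = a, beta_b = b,
      p_two_tailed = p, ci_low = ci[1L], ci_high = ci[2L],
      verdict = if (d >= ci[1L] && d <= ci[2L]) "pass" else "fail",
      alpha = alpha, context = context
    ),
    class = "dw_report"
  )
}

#' Durbin-Watson test of a fitted trend model
#'
#' For an OLS fit, tests the raw residuals against the exact null moments of
#' the design. For a GLS fit, tests the transformed residuals `P e` (with
#' `e = y - X b_GLS` and `P` the symmetric principal root of `S^-1`):
#' `d = e'P'APe / e'S^-1 e`, with moments evaluated on `P X`. A failing
#' verdict means either the correlation model does not capture the error
#' correlation, or the regression model itself is unsuitable.
#'
#' @param fit A `"trend_fit"` from [fit_ols()] or [fit_gls()].
#' @param alpha Two-sided level.
#' @return A `"dw_report"`.
#' @export
dw_test <- function(fit, alpha = 0.05) {
  if (!inherits(fit, "trend_fit")) abort("`fit` must be a trend_fit.")
  gls <- fit$method == "gls" && !is.null(fit$model) && fit$model$kind != "identity"
  if (gls) {
    P <- principal_sqrt_inv(fit$model)
    e_t <- as.numeric(P %*% fit$residuals)
    dw <- dw_statistic(e_t)
    m <- dw_moments(fit$X, fit$model, P = P)
    context <- "gls_transformed"
  } else {
    dw <- dw_statistic(fit$residuals)
    m <- dw_moments(fit$X)
    context <- "ols"
  }
  out <- dw_beta_test(dw$d, m$E_d, m$V_d, alpha = alpha, context = context)
  out$ssrfd <- dw$ssrfd
  out$ssr <- dw$ssr
  out
}

#' @export
print.dw_report <- function(x, ...) {
  cat(sprintf(
    "Durbin-Watson test (%s residuals)\n  d = %.4f  E(d) = %.4f  V(d) = %.5f\n  %.0f%% interval [%.3f, %.3f]  ->  %s\n  two-tailed Pr = %.5g\n",
    x$context, x$d, x$E_d, x$V_d, 100 * (1 - x$alpha), x$ci_low, x$ci_high,
    toupper(x$verdict), x$p_two_tailed
  ))
  invisible(x)
}

#' @export
tidy.dw_report <- function(x, ...) {
  tibble(
    d = x$d, E_d = x$E_d, V_d = x$V_d,
    beta_a = x$beta_a, beta_b = x$beta_b,
    p.value = x$p_two_tailed,
    ci_low = x$ci_low, ci_high = x$ci_high,
    verdict = x$verdict, context = x$context
  )
}

#' @export
glance.dw_report <- function(x, ...) tidy(x)
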