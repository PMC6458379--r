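# Shared least-squares engine: QR fit plus the usual summaries.
ls_engine <- function(X, y, dof, s2_scale = 1) {
  qx <- qr(X)
  b <- qr.coef(qx, y)
  r <- as.numeric(y - X %*% b)
  ssr <- sum(r^2)
  s2 <- s2_scale * ssr / dof
  # relative tolerance: a perfect fit leaves residuals at rounding level
  perfect <- ssr <= 1e-20 * max(sum(y^2), 1)
  # In the whitened metric T'T = S^-1 / s2_scale, so (X'T'TX)^-1 / s2_scale
  # is (X'S^-1X)^-1; the scale cancels in the standard errors:
  # se = s * sqrt(diag[(X'S^-1X)^-1]) = sqrt(ssr/dof) * sqrt(diag[(X'T'TX)^-1]).
  cov_unscaled <- chol2inv(qr.R(qx)) / s2_scale
  se <- sqrt(s2 * diag(cov_unscaled))
  tval <- if (perfect) rep(NA_real_, length(b)) else b / se
  list(
    b = b, se = se, t = tval, s = sqrt(s2), resid = r, dof = dof,
    cov_unscaled = cov_unscaled, perfect = perfect
  )
}

new_trend_fit <- function(est, X, y, method, model = NULL, n = length(y)) {
  k <- design_k(X)
  p <- if (est$perfect) rep(NA_real_, length(est$b)) else 2 * pt(-abs(est$t), est$dof)
  structure(
    list(
      coefficients = est$b, se = est$se, t = est$t, p.value = p,
      sigma = est$s, residuals = est$resid, dof = est$dof,
      n = n, k = k, method = method, model = model,
      X = X, y = y, perfect = est$perfect,
      cov_unscaled = est$cov_unscaled
    ),
    class = "trend_fit"
  )
}

#' Ordinary least-squares fit
#'
#' Fits `y = X b + e` by QR decomposition. The residual standard error is
#' `sqrt(e'e / (N - k - 1))` and coefficient standard errors come from the
#' diagonal of `s^2 (X'X)^-1`. A perfect fit (zero residual sum of squares)
#' is flagged and its t-values reported as `NA` rather than infinite.
#'
#' @param X Design matrix from [poly_design()] or [as_design()].
#' @param y Response vector.
#' @return An object of class `"trend_fit"`; see [tidy.trend_fit()].
#' @export
fit_ols <- function(X, y) {
  y <- as.numeric(y)
  n <- length(y)
  if (n != nrow(X)) abort("`y` must have one value per design row.")
  k <- design_k(X)
  if (n < k + 3L) abort("need at least k + 3 observations.")
  est <- ls_engine(unclass(X), y, dof = n - k - 1L)
  new_trend_fit(est, X, y, method = "ols")
}

#' Generalized least-squares fit with a correlation model
#'
#' Fits `b = (X' S^-1 X)^-1 X' S^-1 y` for a given error-correlation model,
#' by ordinary least squares on a whitened system `(T X, T y)` with
#' `T'T` proportional to `S^-1`. The residuals stored in the result are the
#' untransformed `y - X b`; the residual standard error is
#' `sqrt(e' S^-1 e / (N - k - 1))` on the correlation-matrix scale. With the
#' identity model the computation reduces to [fit_ols()] exactly.
#'
#' @inheritParams fit_ols
#' @param model A [cor_model] object.
#' @return A `"trend_fit"` with `method = "gls"` carrying the model.
#' @export
fit_gls <- function(X, y, model) {
  if (!inherits(model, "cor_model")) abort("`model` must be a cor_model.")
  y <- as.numeric(y)
  n <- length(y)
  if (model$n != n) abort("correlation model size differs from the data.")
  k <- design_k(X)
  if (n < k + 3L) abort("need at least k + 3 observations.")
  if (model$kind == "identity") {
    fit <- fit_ols(X, y)
    fit$method <- "gls"
    fit$model <- model
    return(fit)
  }
  X0 <- unclass(X)
  if (model$kind == "ar1") {
    rho <- model$rho
    Ty <- c(sqrt(1 - rho^2) * y[1L], y[-1L] - rho * y[-n])
    TX <- rbind(sqrt(1 - rho^2) * X0[1L, ], X0[-1L, , drop = FALSE] - rho * X0[-n, , drop = FALSE])
    s2_scale <- 1 / (1 - rho^2)
  } else {
    T <- chol(model$S_inv)
    Ty <- as.numeric(T %*% y)
    TX <- T %*% X0
    s2_scale <- 1
  }
  if (qr(TX)$rank < ncol(TX)) {
    abort("(X' S^-1 X) is not invertible; the correlation model appears unsuitable for this design.")
  }
  est <- ls_engine(TX, Ty, dof = n - k - 1L, s2_scale = s2_scale)
  # report residuals on the original scale
  est$resid <- as.numeric(y - X0 %*% est$b)
  new_trend_fit(est, X, y, method = "gls", model = model, n = n)
}

#' Cochrane-Orcutt estimation
#'
#' Removes AR(1) correlation by subtracting `rho` times the previous
#' observation from each row of `y` and `X`, then fits ordinary least squares
#' on the `N - 1` transformed observations (the first observation is lost).
#' Coefficients and t-values converge to GLS with known `rho` as `N` grows.
#' Only meaningful for equally spaced one-dimensional data.
#'
#' @inheritParams fit_ols
#' @param rho Assumed AR(1) correlation, in (-1, 1).
#' @return A `"trend_fit"` with `method = "cochrane_orcutt"` and `n = N - 1`.
#' @export
cochrane_orcutt <- function(X, y, rho) {
  check_rho(rho)
  y <- as.numeric(y)
  n <- length(y)
  k <- design_k(X)
  if (n - 1L <= k + 1L) abort("too few observations after losing the first one.")
  X0 <- unclass(X)
  Ty <- y[-1L] - rho * y[-n]
  TX <- X0[-1L, , drop = FALSE] - rho * X0[-n, , drop = FALSE]
  est <- ls_engine(TX, Ty, dof = (n - 1L) - k - 1L)
  fit <- new_trend_fit(est, X, y, method = "cochrane_orcutt",
                       model = cor_ar1(rho, n), n = n - 1L)
  fit$residuals <- est$resid   # transformed-scale residuals, length N - 1
  fit
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit: %s>  n = %d, k = %d, residual SE = %s on %d df\n",
    x$method, x$n, x$k, signif(x$sigma, 5), x$dof
  ))
  if (!is.null(x$model) && x$model$kind != "identity") print(x$model)
  print(as.data.frame(tidy(x)), digits = 4)
  if (x$perfect) cat("note: perfect fit; t-values undefined\n")
  invisible(x)
}

#' Tidy a trend fit
#'
#' @param x A `"trend_fit"`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic` and the two-sided `p.value` from the
#'   t-distribution with `N - k - 1` degrees of freedom.
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$t),
    p.value = unname(x$p.value)
  )
}

#' @rdname tidy.trend_fit
#' @return For `glance()`: a one-row tibble with `sigma`, `df.residual`,
#'   `nobs`, `method` and the correlation parameter (`rho` or `r0`) if any.
#' @export
glance.trend_fit <- function(x, ...) {
  tibble(
    sigma = x$sigma,
    df.residual = x$dof,
    nobs = x$n,
    method = x$method,
    rho = if (!is.null(x$model) && x$model$kind == "ar1") x$model$rho else NA_real_,
    r0 = if (!is.null(x$model) && x$model$kind == "exponential") x$model$r0 else NA_real_
  )
}

#' @export
residuals.trend_fit <- function(object, ...) object$residuals

#' @export
coef.trend_fit <- function(object, ...) object$coefficients
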