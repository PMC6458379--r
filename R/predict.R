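#' Prediction interval for a fitted trend model
#'
#' Pointwise 100(1 - alpha)% prediction interval for a new observation at
#' covariates `x0`, following
#' `s_p = sqrt(s^2 + s_b1^2 + sum_{i>=2} s_bi^2 (x0_i - xbar_i)^2)` with
#' bounds at the `t(N - k - 1)` quantiles. The formula assumes mutually
#' uncorrelated explanatory variables, so the fit's design is passed through
#' [decorrelate_design()] and refitted internally (fitted values are
#' unchanged by that transform); new points are mapped through the same
#' centring and decorrelation bookkeeping. With `se_mode = "extrapolated"`
#' the coefficient standard errors are replaced by the extrapolated
#' `2 se_tadw - se_dw` values: supply the correlation models implied by the
#' Durbin-Watson and TADW estimates and both GLS fits are redone on the
#' decorrelated design (the fitted mean then comes from the TADW fit).
#'
#' @param fit A `"trend_fit"` (OLS or GLS) whose design came from
#'   [poly_design()] or [as_design()].
#' @param newx New evaluation points: a vector of raw times for polynomial
#'   designs, or a matrix/data frame of covariate rows.
#' @param level Coverage level, default 0.95.
#' @param se_mode `"standard"` or `"extrapolated"`.
#' @param model_dw,model_tadw [cor_model] objects under the Durbin-Watson
#'   and TADW correlation estimates; required when
#'   `se_mode = "extrapolated"`.
#' @return A tibble of class `"trend_prediction"` with `x0` (first
#'   coordinate of each point), `y0_hat`, `s_p`, `lower`, `upper`.
#' @export
predict_trend <- function(fit, newx, level = 0.95,
                          se_mode = c("standard", "extrapolated"),
                          model_dw = NULL, model_tadw = NULL) {
  se_mode <- match.arg(se_mode)
  if (!inherits(fit, "trend_fit")) abort("`fit` must be a trend_fit.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  Xd <- decorrelate_design(fit$X)
  if (se_mode == "extrapolated") {
    if (is.null(model_dw) || is.null(model_tadw)) {
      abort("`model_dw` and `model_tadw` are required for se_mode = 'extrapolated'.")
    }
    f_dw <- fit_gls(Xd, fit$y, model_dw)
    refit <- fit_gls(Xd, fit$y, model_tadw)
    ex <- extrapolate(f_dw, refit)
    se_b <- ex$se_extrap
  } else {
    refit <- if (fit$method == "gls" && !is.null(fit$model) && fit$model$kind != "identity") {
      fit_gls(Xd, fit$y, fit$model)
    } else {
      fit_ols(Xd, fit$y)
    }
    se_b <- refit$se
  }
  M <- design_rows(Xd, newx)
  if (any(!is.finite(M))) abort("`newx` contains non-finite values.")
  xbar <- colMeans(unclass(Xd))
  y0 <- as.numeric(M %*% refit$coefficients)
  dev2 <- sweep(M[, -1L, drop = FALSE], 2L, xbar[-1L])^2
  s_p <- sqrt(refit$sigma^2 + se_b[1L]^2 +
    as.numeric(dev2 %*% se_b[-1L]^2))
  tq <- qt(1 - (1 - level) / 2, fit$dof)
  out <- tibble(
    x0 = if (is.null(dim(newx))) as.numeric(newx) else as.numeric(as.matrix(newx)[, 1L]),
    y0_hat = y0, s_p = s_p,
    lower = y0 - tq * s_p, upper = y0 + tq * s_p
  )
  structure(out,
    class = c("trend_prediction", class(out)),
    level = level, se_mode = se_mode, dof = fit$dof
  )
}

#' @export
autoplot.trend_prediction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x0, y = .data$y0_hat)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "x", y = "prediction",
      title = sprintf("%.0f%% prediction interval", 100 * attr(object, "level"))
    )
}

#' @export
autoplot.semivariogram_fit <- function(object, ...) {
  cls <- object$classes
  grid <- tibble(r = seq(0, max(cls$mid), length.out = 200))
  grid$gamma <- object$sill * (1 - exp(-grid$r / object$r0_hat))
  ggplot2::ggplot(cls, ggplot2::aes(x = .data$mid, y = .data$gamma_mean)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$r, y = .data$gamma), colour = "firebrick") +
    ggplot2::geom_hline(yintercept = object$sill, linetype = 2) +
    ggplot2::labs(x = "distance", y = "semivariance", size = "pairs")
}

#' @export
autoplot.nnn_path <- function(object, ...) {
  cc <- object$coords
  df <- tibble(
    x = cc[, 1L],
    y = if (ncol(cc) >= 2L) cc[, 2L] else 0,
    step = seq_len(nrow(cc))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$step)) +
    ggplot2::labs(title = "nearest new neighbour path", colour = "visit")
}
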