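#' Build a centred polynomial design matrix
#'
#' Constructs the design matrix for a polynomial trend model in time: a
#' leading column of ones, then powers of the mean-centred times. Every
#' non-intercept column is additionally mean-centred, which changes only the
#' fitted intercept but keeps the coefficient covariance well conditioned and
#' makes the column means exactly zero for use in prediction intervals.
#'
#' @param times Numeric vector of observation times (any spacing).
#' @param degree Polynomial degree, an integer `>= 0`. `degree = 0` gives an
#'   intercept-only design.
#' @return A numeric matrix of class `"trend_design"` with `degree + 1`
#'   columns, and attributes `k` (number of non-intercept parameters),
#'   `centered`, `decorrelated`, plus the transform metadata needed to map raw
#'   times for new points (`t_center`, `powers`, `col_centers`).
#' @examples
#' X <- poly_design(1977:2016, degree = 2)
#' colMeans(X[, -1])   # zero to machine precision
#' @export
poly_design <- function(times, degree = 1L) {
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times))) abort("`times` must be finite.")
  degree <- as.integer(degree)
  if (degree < 0L) abort("`degree` must be >= 0.")
  n <- length(times)
  if (degree + 1L >= n) abort("`degree` + 1 must be smaller than the number of observations.")
  if (length(unique(times)) < degree + 1L) {
    abort(sprintf("need at least %d distinct time values for degree %d.", degree + 1L, degree))
  }
  tc <- mean(times)
  td <- times - tc
  X <- vapply(0:degree, function(p) td^p, numeric(n))
  col_centers <- c(0, if (degree > 0L) colMeans(X[, -1L, drop = FALSE]) else NULL)
  if (degree > 0L) X[, -1L] <- sweep(X[, -1L, drop = FALSE], 2L, col_centers[-1L])
  colnames(X) <- c("(Intercept)", if (degree > 0L) paste0("t", ifelse(1:degree == 1, "", paste0("^", 1:degree))))
  new_design(X,
    k = degree, centered = TRUE, decorrelated = FALSE,
    t_center = tc, powers = 0:degree, col_centers = col_centers
  )
}

new_design <- function(X, ...) {
  att <- list(...)
  for (nm in names(att)) attr(X, nm) <- att[[nm]]
  class(X) <- c("trend_design", class(X))
  check_design_rank(X)
  X
}

#' Wrap an arbitrary design matrix
#'
#' Adds the intercept column if absent and tags the matrix for use with
#' [fit_ols()] and [fit_gls()]. Non-intercept columns are mean-centred by
#' default.
#'
#' @param X Numeric matrix (or data frame) of covariate columns, without
#'   intercept.
#' @param center Centre non-intercept columns? Default `TRUE`.
#' @return A `"trend_design"` matrix.
#' @export
as_design <- function(X, center = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  col_centers <- if (center) colMeans(X) else numeric(ncol(X))
  if (center) X <- sweep(X, 2L, col_centers)
  X <- cbind("(Intercept)" = 1, X)
  new_design(X,
    k = ncol(X) - 1L, centered = center, decorrelated = FALSE,
    col_centers = c(0, col_centers)
  )
}

check_design_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    abort(sprintf(
      "design matrix is rank deficient: column(s) %s are linearly dependent on the others.",
      paste0("'", bad, "'", collapse = ", ")
    ))
  }
  invisible(X)
}

design_k <- function(X) {
  k <- attr(X, "k")
  if (is.null(k)) ncol(X) - 1L else k
}

#' Sequentially decorrelate design columns
#'
#' Residualizes each non-intercept column on all preceding columns (ordinary
#' least squares), making the columns mutually orthogonal. Fitted values of
#' any subsequent OLS or GLS regression are unchanged; the purpose is an
#' accurate prediction interval, whose formula assumes uncorrelated
#' explanatory variables.
#'
#' @param X A `"trend_design"` matrix.
#' @return The decorrelated design, with attribute `decor_coefs` recording the
#'   per-column regression coefficients so new points can be mapped through
#'   the same transform.
#' @export
decorrelate_design <- function(X) {
  X0 <- unclass(X)
  p <- ncol(X0)
  coefs <- vector("list", p)
  out <- X0
  for (j in seq_len(p)[-1L]) {
    prev <- out[, seq_len(j - 1L), drop = FALSE]
    cf <- qr.coef(qr(prev), X0[, j])
    cf[is.na(cf)] <- 0
    out[, j] <- X0[, j] - prev %*% cf
    coefs[[j]] <- cf
  }
  res <- X
  res[] <- out
  attr(res, "decorrelated") <- TRUE
  attr(res, "decor_coefs") <- coefs
  res
}

# Map raw times (or covariate rows) through the design's stored transforms,
# producing rows comparable with the fitted coefficients.
design_rows <- function(X, newx) {
  powers <- attr(X, "powers")
  if (!is.null(powers)) {
    td <- as.numeric(newx) - attr(X, "t_center")
    M <- outer(td, powers, "^")
  } else {
    M <- as.matrix(newx)
    if (ncol(M) != ncol(X) - 1L) abort("`newx` must have one column per non-intercept design column.")
    M <- cbind(1, M)
  }
  cc <- attr(X, "col_centers")
  if (!is.null(cc)) M <- sweep(M, 2L, cc)
  if (isTRUE(attr(X, "decorrelated"))) {
    coefs <- attr(X, "decor_coefs")
    for (j in seq_len(ncol(M))[-1L]) {
      cf <- coefs[[j]]
      if (!is.null(cf)) M[, j] <- M[, j] - M[, seq_len(j - 1L), drop = FALSE] %*% cf
    }
  }
  colnames(M) <- colnames(X)
  M
}
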