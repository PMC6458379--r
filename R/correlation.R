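#' AR(1) correlation matrix
#'
#' Correlation matrix of a stationary first-order autoregressive process:
#' `S[i, j] = rho^|i - j|`.
#'
#' @param rho Lag-1 autocorrelation, in (-1, 1).
#' @param n Number of observations (`>= 2`).
#' @return An `n x n` correlation matrix.
#' @export
ar1_correlation <- function(rho, n) {
  check_rho(rho)
  if (n < 2L) abort("`n` must be >= 2.")
  idx <- seq_len(n)
  rho^abs(outer(idx, idx, "-"))
}

#' Closed-form inverse of the AR(1) correlation matrix
#'
#' The inverse is tridiagonal: `1/(1 - rho^2)` times a matrix with 1 at the
#' two diagonal corners, `1 + rho^2` on the interior diagonal and `-rho` on
#' the sub- and superdiagonals.
#'
#' @inheritParams ar1_correlation
#' @return The `n x n` inverse correlation matrix.
#' @export
ar1_inverse <- function(rho, n) {
  check_rho(rho)
  if (n < 2L) abort("`n` must be >= 2.")
  M <- diag(c(1, rep(1 + rho^2, n - 2L), 1))
  idx <- seq_len(n - 1L)
  M[cbind(idx, idx + 1L)] <- -rho
  M[cbind(idx + 1L, idx)] <- -rho
  M / (1 - rho^2)
}

#' Pairwise distance matrix for 1-3 dimensional coordinates
#'
#' @param coords Numeric matrix with one row per point and 1-3 columns.
#' @param metric `"euclidean"`, or `"greatcircle"` for lon/lat input in
#'   degrees (haversine distances on a sphere of radius 6371 km, returned in
#'   km).
#' @return Symmetric matrix of distances.
#' @export
distance_matrix <- function(coords, metric = c("euclidean", "greatcircle")) {
  metric <- match.arg(metric)
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) abort("`coords` must be finite.")
  if (ncol(coords) < 1L || ncol(coords) > 3L) abort("`coords` must have 1-3 columns.")
  if (metric == "greatcircle") {
    if (ncol(coords) != 2L) abort("great-circle distance requires two columns: longitude, latitude (degrees).")
    n <- nrow(coords)
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      d <- geosphere::distHaversine(coords[i, ], coords[(i + 1L):n, , drop = FALSE], r = 6371000) / 1000
      D[i, (i + 1L):n] <- d
      D[(i + 1L):n, i] <- d
    }
    D
  } else {
    unname(as.matrix(dist(coords)))
  }
}

#' Exponential spatial correlation matrix
#'
#' Radial-basis correlation `exp(-r_ij / r0)` between points, generalizing
#' the AR(1) model to scattered locations: on a unit-spaced 1-D grid with
#' `r0 = -1/log(rho)` it reproduces [ar1_correlation()] exactly. Pairs of
#' observations from different co-location groups (e.g. two datasets measured
#' at the same places) are separated by an additional pseudo-distance
#' `r_d = k_d * r0`, entering through
#' `exp(-sqrt((r_ij/r0)^2 + k_d^2))`; diagonal entries remain exactly 1.
#'
#' @param coords Matrix of coordinates (rows = points, 1-3 columns), or a
#'   pre-computed distance matrix via `dist_matrix`.
#' @param r0 Correlation length, in coordinate units (`> 0`).
#' @param kd Co-location pseudo-distance ratio `r_d / r0` (`>= 0`). Ignored
#'   unless `groups` is supplied or `kd > 0` with `groups` marking datasets.
#' @param groups Optional vector labelling which dataset each row belongs to;
#'   the `kd` penalty applies to pairs with differing labels.
#' @param metric Distance metric, see [distance_matrix()].
#' @param dist_matrix Optional distance matrix, overriding `coords`.
#' @return A correlation matrix with unit diagonal.
#' @export
exponential_correlation <- function(coords = NULL, r0, kd = 0, groups = NULL,
                                    metric = "euclidean", dist_matrix = NULL) {
  if (!is.numeric(r0) || length(r0) != 1L || r0 <= 0) abort("`r0` must be a single positive value.")
  if (kd < 0) abort("`kd` must be >= 0.")
  D <- if (is.null(dist_matrix)) distance_matrix(coords, metric) else as.matrix(dist_matrix)
  S <- exp(-D / r0)
  if (kd > 0) {
    cross <- if (is.null(groups)) {
      matrix(TRUE, nrow(D), ncol(D))
    } else {
      outer(groups, groups, "!=")
    }
    S[cross] <- exp(-sqrt((D[cross] / r0)^2 + kd^2))
  }
  diag(S) <- 1
  S
}

#' Correlation model constructors
#'
#' A correlation model bundles the error-correlation matrix `S`, its inverse
#' and (on demand) the symmetric principal square root `P` of `S^-1` used by
#' the transformed-residual Durbin-Watson test. `cor_identity()` describes
#' uncorrelated errors, `cor_ar1()` a first-order autoregressive process, and
#' `cor_exponential()` the exponential radial model for scattered points.
#'
#' @param n Number of observations.
#' @param rho AR(1) lag-1 correlation in (-1, 1).
#' @inheritParams exponential_correlation
#' @return An object of class `"cor_model"`.
#' @name cor_model
NULL

#' @rdname cor_model
#' @export
cor_identity <- function(n) {
  structure(list(kind = "identity", n = as.integer(n)), class = "cor_model")
}

#' @rdname cor_model
#' @export
cor_ar1 <- function(rho, n) {
  rho <- clamp_rho(check_rho(rho), warn = FALSE)
  structure(list(kind = "ar1", rho = rho, n = as.integer(n)), class = "cor_model")
}

#' @rdname cor_model
#' @export
cor_exponential <- function(coords = NULL, r0, kd = 0, groups = NULL,
                            metric = "euclidean", dist_matrix = NULL) {
  S <- exponential_correlation(coords, r0, kd, groups, metric, dist_matrix)
  S_inv <- tryCatch(
    chol2inv(chol(S)),
    error = function(e) {
      abort(paste0(
        "exponential correlation matrix is numerically singular (r0 = ", signif(r0, 4),
        "); revise the correlation or regression model."
      ))
    }
  )
  structure(
    list(
      kind = "exponential", r0 = r0, kd = kd, rd = kd * r0,
      groups = groups, n = nrow(S), S = S, S_inv = S_inv
    ),
    class = "cor_model"
  )
}

#' @export
print.cor_model <- function(x, ...) {
  cat("<cor_model:", x$kind, ">", sep = "")
  if (x$kind == "ar1") cat(" rho =", signif(x$rho, 4))
  if (x$kind == "exponential") {
    cat(" r0 =", signif(x$r0, 4))
    if (x$kd > 0) cat(", kd =", signif(x$kd, 4))
  }
  cat(", n =", x$n, "\n")
  invisible(x)
}

cor_S <- function(model) {
  switch(model$kind,
    identity = diag(model$n),
    ar1 = ar1_correlation(model$rho, model$n),
    exponential = model$S
  )
}

cor_S_inv <- function(model) {
  switch(model$kind,
    identity = diag(model$n),
    ar1 = ar1_inverse(model$rho, model$n),
    exponential = model$S_inv
  )
}

#' Symmetric principal square root of the inverse correlation matrix
#'
#' Returns the unique symmetric positive-definite `P` with `P %*% P = S^-1`
#' (hence `t(P) %*% P = S^-1`), computed from the symmetric eigendecomposition
#' with the non-negative root of each eigenvalue. This is the transform that
#' makes the transformed-residual Durbin-Watson statistic well defined, since
#' different factorizations of `S^-1` give slightly different `d`.
#'
#' @param model A `"cor_model"`, or a symmetric positive-definite matrix
#'   taken to be `S^-1` itself.
#' @return A symmetric matrix `P`.
#' @export
principal_sqrt_inv <- function(model) {
  S_inv <- if (inherits(model, "cor_model")) cor_S_inv(model) else as.matrix(model)
  ee <- eigen((S_inv + t(S_inv)) / 2, symmetric = TRUE)
  lam <- ee$values
  if (any(lam < -1e-8 * max(abs(lam)))) {
    abort("`S^-1` has a negative eigenvalue beyond tolerance; it is not positive definite.")
  }
  ee$vectors %*% (sqrt(pmax(lam, 0)) * t(ee$vectors))
}

# Whitening transform T with T'T proportional to S^-1 -- enough for GLS
# coefficients and t-values. For AR(1), the stationarity-scaled
# first-difference form gives T'T = (1 - rho^2) S^-1 in O(n); the attribute
# records the proportionality constant so the residual SE can be put on the
# correlation-matrix scale.
cor_whitener <- function(model) {
  switch(model$kind,
    identity = structure(diag(model$n), scale = 1),
    ar1 = {
      n <- model$n
      rho <- model$rho
      T <- diag(n)
      T[1L, 1L] <- sqrt(1 - rho^2)
      T[cbind(2:n, 1:(n - 1L))] <- -rho
      structure(T, scale = 1 - rho^2)
    },
    exponential = structure(chol(model$S_inv), scale = 1)
  )
}
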