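#' Nearest new neighbour path through scattered points
#'
#' Generalizes "successive residuals" to space: start at the point with the
#' greatest sum of distances to all other points, then repeatedly step to
#' the nearest point not already visited. Points closer together than
#' `tol` times the bounding-box diagonal are merged into a single path node
#' whose value is the mean of its members; the returned reduction matrix
#' `R` (one row per path node, rows summing to 1) performs both the
#' path-ordering and the within-node averaging. Ties (equidistant
#' candidates, tied start points) are broken by lowest row index.
#'
#' @param coords Coordinate matrix (1-3 columns) or vector.
#' @param metric Distance metric, see [distance_matrix()].
#' @param tol Relative co-location tolerance (default `1e-9` of the
#'   bounding-box diagonal).
#' @return An object of class `"nnn_path"`: `order` (visiting order of the
#'   merged locations, as indices into the merged set), `merge_map` (list of
#'   original row indices per merged location, in path order), `m_coloc`
#'   (rows absorbed by merging), `r_bar` (mean distance between consecutive
#'   path nodes), `start_index`, `R` (reduction matrix, path-ordered),
#'   `dist` (merged distance matrix in path order), `coords` (merged
#'   coordinates in path order), `n` (original rows).
#' @export
nnn_path <- function(coords, metric = "euclidean", tol = 1e-9) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) abort("need at least 3 points.")
  D_full <- distance_matrix(coords, metric)
  diam <- max(D_full)
  if (diam == 0) abort("all points are co-located; a path is undefined.")
  # merge co-located rows
  grp <- rep(NA_integer_, n)
  g <- 0L
  for (i in seq_len(n)) {
    if (is.na(grp[i])) {
      g <- g + 1L
      members <- which(is.na(grp) & D_full[i, ] <= tol * diam)
      grp[members] <- g
    }
  }
  merge_map0 <- split(seq_len(n), grp)
  m <- length(merge_map0)
  if (m < 3L) abort("fewer than 3 distinct locations after merging co-located points.")
  centroids <- do.call(rbind, lapply(merge_map0, function(ix) colMeans(coords[ix, , drop = FALSE])))
  D <- distance_matrix(centroids, metric)
  start <- which.max(rowSums(D)) # which.max takes the lowest index on ties
  ord <- integer(m)
  ord[1L] <- start
  remaining <- setdiff(seq_len(m), start)
  for (i in 2:m) {
    nxt <- remaining[which.min(D[ord[i - 1L], remaining])]
    ord[i] <- nxt
    remaining <- remaining[remaining != nxt]
  }
  R <- matrix(0, m, n)
  for (i in seq_len(m)) {
    ix <- merge_map0[[ord[i]]]
    R[i, ix] <- 1 / length(ix)
  }
  steps <- D[cbind(ord[-m], ord[-1L])]
  structure(
    list(
      order = ord,
      merge_map = merge_map0[ord],
      m_coloc = n - m,
      r_bar = mean(steps),
      start_index = start,
      R = R,
      dist = D[ord, ord],
      coords = centroids[ord, , drop = FALSE],
      coords_full = coords,
      metric = metric,
      n = n
    ),
    class = "nnn_path"
  )
}

#' @export
print.nnn_path <- function(x, ...) {
  cat(sprintf(
    "<nnn_path> %d points -> %d path nodes (%d merged), r_bar = %s\n",
    x$n, length(x$order), x$m_coloc, signif(x$r_bar, 5)
  ))
  invisible(x)
}

#' Spatial Durbin-Watson statistic along a nearest new neighbour path
#'
#' Orders (and, for co-located points, averages) the residuals with the
#' path's reduction matrix and computes `d = SSRFD / SSR` over the
#' path-ordered values. On equally spaced 1-D data with no merges this
#' equals the time-series statistic exactly.
#'
#' @param e Residual vector (original ordering, one per data row).
#' @param path An [nnn_path()] object.
#' @return A list with `d`, `ssrfd`, `ssr` and the reduced residuals `e_r`.
#' @export
spatial_dw <- function(e, path) {
  if (!inherits(path, "nnn_path")) abort("`path` must be an nnn_path.")
  if (length(e) != path$n) abort("`e` must have one residual per original data row.")
  e_r <- as.numeric(path$R %*% e)
  if (length(e_r) < 3L) abort("fewer than 3 path nodes.")
  out <- dw_statistic(e_r)
  out$e_r <- e_r
  out
}

#' Estimate the exponential correlation length r0 from a path
#'
#' Applies a Durbin-Watson-type estimator to the path-ordered (reduced)
#' residuals and converts the implied lag correlation to a correlation
#' length via `r0 = -r_bar / log(rho)`, `r_bar` being the mean distance
#' between nearest new neighbours. The `"tadw"` variant uses the exact null
#' moments of the reduced, path-ordered design.
#'
#' @param e Residual vector (original ordering).
#' @param path An [nnn_path()].
#' @param X Design matrix of the fit that produced `e`.
#' @param method `"dw"` or `"tadw"`.
#' @return A list with `r0`, `rho`, `d`, `E_d`, `V_d` (moments `NA` for
#'   `"dw"`). If the estimated correlation is not positive, `r0` is `NA`
#'   and `positive = FALSE`: there is no positive spatial correlation for
#'   the exponential model to represent, and the caller should fall back to
#'   OLS.
#' @export
estimate_r0 <- function(e, path, X, method = c("dw", "tadw")) {
  method <- match.arg(method)
  sdw <- spatial_dw(e, path)
  Xr <- reduce_design(X, path)
  E_d <- V_d <- NA_real_
  if (method == "dw") {
    rho <- rho_dw(sdw$d)$rho
  } else {
    m <- dw_moments(Xr)
    E_d <- m$E_d
    V_d <- m$V_d
    rho <- rho_tadw(sdw$d, E_d, V_d, nrow(Xr), design_k(Xr))$rho
  }
  if (rho <= 0) {
    return(list(r0 = NA_real_, rho = rho, d = sdw$d, E_d = E_d, V_d = V_d, positive = FALSE))
  }
  list(r0 = -path$r_bar / log(rho), rho = rho, d = sdw$d, E_d = E_d, V_d = V_d, positive = TRUE)
}

# path-order (and average co-located rows of) a design matrix, keeping the
# design attributes needed downstream
reduce_design <- function(X, path) {
  Xr <- path$R %*% unclass(X)
  colnames(Xr) <- colnames(X)
  attr(Xr, "k") <- design_k(X)
  class(Xr) <- c("trend_design", class(Xr))
  Xr
}

#' Transformed-residual Durbin-Watson test for a spatial GLS fit
#'
#' Validity test of a GLS fit with an exponential correlation model on
#' scattered data. The residuals and design are first reduced to the
#' nearest-new-neighbour path order (averaging co-located points), then
#' whitened with the symmetric principal root of the reduced system's
#' inverse correlation matrix; the Durbin-Watson statistic of the whitened
#' values is referred to the null moments of the reduced, whitened design.
#' On equally spaced 1-D data with no merges this reproduces the
#' time-series transformed-residual test exactly.
#'
#' @param fit GLS `"trend_fit"` with an exponential [cor_model].
#' @param path The [nnn_path()] of the data locations.
#' @param X The (unreduced) design matrix of the fit.
#' @param alpha Two-sided level.
#' @return A `"dw_report"` with context `"gls_transformed"`.
#' @export
spatial_dw_test_gls <- function(fit, path, X = fit$X, alpha = 0.05) {
  if (!inherits(fit, "trend_fit") || fit$method != "gls") abort("`fit` must be a GLS trend_fit.")
  # co-located rows are merged away in the reduced system, so kd plays no role
  model_r <- cor_exponential(dist_matrix = path$dist, r0 = fit$model$r0)
  Xr <- reduce_design(X, path)
  e_r <- as.numeric(path$R %*% fit$residuals)
  P_r <- principal_sqrt_inv(model_r)
  dw <- dw_statistic(as.numeric(P_r %*% e_r))
  m <- dw_moments(Xr, model_r, P = P_r)
  out <- dw_beta_test(dw$d, m$E_d, m$V_d, alpha = alpha, context = "gls_transformed")
  out$ssrfd <- dw$ssrfd
  out$ssr <- dw$ssr
  out
}

#' Empirical semivariogram with exponential-model fit
#'
#' Computes `gamma_ij = (e_i - e_j)^2 / 2` for all pairs, averages within
#' equal-width distance classes spanning `(0, max distance / 2]`, and fits
#' the exponential model `gamma(r) = sill * (1 - exp(-r / r0))` by
#' inverse-distance-squared weighted least squares on the class means, with
#' the sill fixed at the residual variance.
#'
#' @param e Residual vector.
#' @param coords Coordinates (or distances via `dist_matrix`).
#' @param n_classes Number of distance classes (default 10).
#' @param sill Residual variance; defaults to `sum(e^2) / (length(e) - 1)`.
#'   Pass the fit's `sigma^2` when available.
#' @param metric Distance metric.
#' @param dist_matrix Optional pre-computed distance matrix.
#' @return A `"semivariogram_fit"`: tibble of class mid-distances, mean
#'   `gamma`, pair counts and weights, plus `sill`, `r0_hat` and a
#'   `converged` flag (`FALSE` for a flat field with no rise towards the
#'   sill).
#' @export
semivariogram <- function(e, coords = NULL, n_classes = 10L, sill = NULL,
                          metric = "euclidean", dist_matrix = NULL) {
  e <- as.numeric(e)
  D <- if (is.null(dist_matrix)) distance_matrix(coords, metric) else as.matrix(dist_matrix)
  if (is.null(sill)) sill <- sum(e^2) / (length(e) - 1)
  ut <- upper.tri(D)
  r <- D[ut]
  gam <- outer(e, e, "-")[ut]^2 / 2
  rmax <- max(r) / 2
  keep <- r > 0 & r <= rmax
  breaks <- seq(0, rmax, length.out = n_classes + 1L)
  cls <- cut(r[keep], breaks, include.lowest = FALSE, labels = FALSE)
  tab <- tibble(class = cls, r = r[keep], gamma = gam[keep]) |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      mid = breaks[.data$class[1L]] + diff(breaks)[1L] / 2,
      gamma_mean = mean(.data$gamma),
      n_pairs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(weight = 1 / .data$mid^2)
  if (nrow(tab) < 2L) abort("need at least 2 non-empty distance classes.")
  obj <- function(log_r0) {
    pred <- sill * (1 - exp(-tab$mid / exp(log_r0)))
    sum(tab$weight * (tab$gamma_mean - pred)^2)
  }
  # flat-field guard: all class means at or above the sill carry no range
  # information
  converged <- any(tab$gamma_mean < sill)
  opt <- optimize(obj, lower = log(min(tab$mid) / 100), upper = log(max(tab$mid) * 100))
  structure(
    list(
      classes = tab, sill = sill, r0_hat = exp(opt$minimum),
      objective = opt$objective, converged = converged
    ),
    class = "semivariogram_fit"
  )
}

#' @export
print.semivariogram_fit <- function(x, ...) {
  cat(sprintf(
    "<semivariogram_fit> sill = %s, r0_hat = %s (%s)\n",
    signif(x$sill, 5), signif(x$r0_hat, 5),
    if (x$converged) "ok" else "fit-failed: no class below the sill"
  ))
  print(as.data.frame(x$classes), digits = 4)
  invisible(x)
}

#' @export
tidy.semivariogram_fit <- function(x, ...) x$classes

#' @export
glance.semivariogram_fit <- function(x, ...) {
  tibble(sill = x$sill, r0_hat = x$r0_hat, converged = x$converged)
}

#' @rdname semivariogram
#' @return For `semivariogram_cloud()`: a tibble of all pairs with their
#'   separation `r` and semivariance `gamma = (e_i - e_j)^2 / 2`.
#' @export
semivariogram_cloud <- function(e, coords = NULL, metric = "euclidean", dist_matrix = NULL) {
  e <- as.numeric(e)
  D <- if (is.null(dist_matrix)) distance_matrix(coords, metric) else as.matrix(dist_matrix)
  ut <- upper.tri(D)
  tibble(r = D[ut], gamma = outer(e, e, "-")[ut]^2 / 2)
}

#' Co-location pseudo-distance ratio k_d
#'
#' From `m` pairs of residuals observed at identical locations (typically
#' one member from each of two datasets), estimates the ratio
#' `k_d = r_d / r0` encoding the imperfect correlation between datasets:
#' `k_d = -log(1 - sum((e_i - e_j)^2) / (2 m sigma2_e))`. When the mean
#' squared pair difference reaches or exceeds `2 sigma2_e` the datasets are
#' effectively uncorrelated at zero distance; the log argument is clamped
#' to a small floor and a warning is issued.
#'
#' @param e Residual vector.
#' @param pairs Two-column integer matrix of co-located row index pairs.
#' @param sigma2_e Residual variance (> 0).
#' @return `k_d` (a single number).
#' @export
colocated_kd <- function(e, pairs, sigma2_e) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L || nrow(pairs) < 1L) abort("`pairs` must be an m x 2 index matrix with m >= 1.")
  if (sigma2_e <= 0) abort("`sigma2_e` must be positive.")
  m <- nrow(pairs)
  ssq <- sum((e[pairs[, 1L]] - e[pairs[, 2L]])^2)
  arg <- 1 - ssq / (2 * m * sigma2_e)
  if (arg <= 0) {
    warn("co-located pairs are effectively uncorrelated at zero distance; clamping k_d.")
    arg <- 1e-6
  }
  -log(arg)
}
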