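# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: pseudo-inverse solves, dense matrix algebra,
# exhaustive greedy walks, grid searches.

# least-squares coefficients via SVD pseudo-inverse
pinv_coef <- function(X, y) {
  sv <- svd(X)
  keep <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  as.numeric(sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep]))
}

# matrix rank from singular values
svd_rank <- function(X) {
  d <- svd(X)$d
  sum(d > max(dim(X)) * .Machine$double.eps * d[1])
}

# greedy nearest-new-neighbour walk, written independently (no merging)
greedy_walk <- function(coords) {
  D <- as.matrix(dist(coords))
  n <- nrow(D)
  cur <- which.max(colSums(D))
  ord <- cur
  while (length(ord) < n) {
    cand <- setdiff(seq_len(n), ord)
    cur <- cand[which.min(D[cur, cand])]
    ord <- c(ord, cur)
  }
  ord
}

# profile conditional log-likelihood of rho (conditioning on the first
# observation; beta profiled out by OLS on the differenced system)
cond_ll <- function(rho, design, y) {
  design <- unclass(design)
  n <- length(y)
  Ty <- y[-1] - rho * y[-n]
  TX <- design[-1, , drop = FALSE] - rho * design[-n, , drop = FALSE]
  rss <- sum(qr.resid(qr(TX), Ty)^2)
  -(n - 1) / 2 * log(rss)
}

grid_ml_oracle <- function(design, y, grid = seq(-0.98, 0.98, by = 0.002)) {
  ll <- vapply(grid, cond_ll, numeric(1), design = design, y = y)
  grid[which.max(ll)]
}

# dense-matrix GLS coefficient oracle: (X'S^-1X)^-1 X'S^-1 y via solve()
gls_coef_oracle <- function(X, y, S) {
  X <- unclass(X)
  Si <- solve(S)
  as.numeric(solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y))
}

# tag a raw matrix as a design without centring (bypasses as_design)
as_design_raw <- function(M) {
  attr(M, "k") <- ncol(M) - 1L
  class(M) <- c("trend_design", class(M))
  M
}

# AR(1) noise written independently of simulate_ar1 (explicit loop)
ar1_loop <- function(n, rho) {
  z <- rnorm(n)
  e <- numeric(n)
  e[1] <- z[1] / sqrt(1 - rho^2)
  for (i in 2:n) e[i] <- z[i] + rho * e[i - 1]
  e
}
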