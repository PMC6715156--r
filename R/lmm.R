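#' Fit the null (no-QTL) linear mixed model
#'
#' Model `y = X beta + u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)`.  The variance ratio
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` is estimated by REML through
#' the eigendecomposition of `K` and one-dimensional optimization on
#' `[0, 0.999]`.  When the likelihood is flat in `h2` (e.g. `K = I`) the
#' boundary convention `h2 = 0` is returned.
#'
#' @param y numeric response (no missing values; drop them first).
#' @param X design matrix including the intercept (full rank).
#' @param K symmetric positive semidefinite kinship matrix.
#' @return list: `h2`, `loglik` (REML, up to a constant), `sigma2g`,
#'   `sigma2e`, `beta` (GLS estimates at the optimum).
#' @export
fit_null_lmm <- function(y, X, K) {
  stopifnot(length(y) == nrow(X), nrow(K) == length(y))
  if (anyNA(y) || anyNA(X)) stop("missing values; drop them before fitting")
  if (qr(X)$rank < ncol(X)) stop("covariate design is rank deficient")
  e <- eigen_kinship(K)
  yr <- crossprod(e$U, y)
  Xr <- crossprod(e$U, X)
  res <- reml_h2(drop(yr), Xr, e$d)
  ## GLS coefficients at the optimum
  w <- 1 / (res$h2 * e$d + 1 - res$h2)
  sw <- sqrt(w)
  fit <- lm.fit(Xr * sw, drop(yr) * sw)
  c(res, list(beta = coef(fit)))
}

eigen_kinship <- function(K) {
  if (max(abs(K - t(K))) > 1e-10) stop("kinship matrix is not symmetric")
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("kinship matrix is not positive semidefinite")
  list(U = e$vectors, d = pmax(e$values, 0))
}

## REML profile over h2 on rotated data; returns h2, loglik, variances
reml_h2 <- function(yr, Xr, d, tol = 1e-6) {
  n <- length(yr)
  p <- ncol(Xr)
  ll <- function(h2) {
    v <- h2 * d + (1 - h2)
    sw <- 1 / sqrt(v)
    Xw <- Xr * sw
    qx <- qr(Xw)
    if (qx$rank < p) return(-Inf)
    rss <- sum(qr.resid(qx, yr * sw)^2)
    if (rss < 1e-12 * max(1, sum((yr * sw)^2)))
      stop("zero residual variance after covariates")
    -0.5 * ((n - p) * log(rss / (n - p)) + sum(log(v)) +
              2 * sum(log(abs(diag(qr.R(qx))))))
  }
  ll0 <- ll(0)
  opt <- optimize(ll, c(0, 0.999), maximum = TRUE, tol = 1e-5)
  if (opt$objective - ll0 < tol) {
    h2 <- 0; lmax <- ll0
  } else {
    h2 <- opt$maximum; lmax <- opt$objective
  }
  v <- h2 * d + (1 - h2)
  sw <- 1 / sqrt(v)
  qx <- qr(Xr * sw)
  s2 <- sum(qr.resid(qx, yr * sw)^2) / (n - p)
  list(h2 = h2, loglik = lmax, sigma2g = h2 * s2, sigma2e = (1 - h2) * s2)
}
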