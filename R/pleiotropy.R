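#' Profile likelihood surface for pleiotropy vs two linked loci
#'
#' For every ordered pair of positions `(lambda1, lambda2)` in the scanned
#' interval, trait 1 is regressed on the founder dosages at `lambda1` and
#' trait 2 on the dosages at `lambda2`, with shared additive covariates and
#' an unstructured 2x2 residual covariance (iterated feasible GLS).  The
#' likelihood ratio statistic, in log10 units, is the surface maximum minus
#' the maximum along the diagonal `lambda1 = lambda2` (the pleiotropy
#' null); the null is a subset of the alternative, so `lrt >= 0`.
#'
#' @param y1,y2 phenotype vectors aligned with `dosage$individuals`;
#'   incomplete pairs are dropped.
#' @param dosage a `founder_dosage` object.
#' @param markers character vector (>= 2) of marker ids defining the
#'   scanned interval, typically the union of the two traits' support
#'   intervals padded by ~2 cM.
#' @param covariates optional covariate data frame.
#' @param niter feasible-GLS iterations per grid cell (default 4).
#' @return list of class `"pleiotropy_profile"`: `surface` (k x k log10
#'   profile likelihood, rows = trait-1 position), `lrt`, `argmax`
#'   (marker pair at the surface maximum), `diag_argmax`, `markers`, `n`.
#' @export
bivariate_profile <- function(y1, y2, dosage, markers, covariates = NULL,
                              niter = 4) {
  if (length(markers) < 2)
    stop("interval must contain >= 2 markers")
  if (!all(markers %in% dosage$map$marker))
    stop("marker(s) not in map: ",
         paste(setdiff(markers, dosage$map$marker), collapse = ", "))
  n_all <- length(dosage$individuals)
  stopifnot(length(y1) == n_all, length(y2) == n_all)
  ok <- complete.cases(y1, y2)
  if (sum(ok) < 3) stop("fewer than 3 complete trait pairs")
  parts <- pleio_parts(dosage, markers, covariates, which(ok))
  yy <- cbind(y1[ok], y2[ok])
  surf <- pleio_surface(parts, yy, niter)
  dimnames(surf) <- list(markers, markers)
  lrt <- surface_lrt(surf)
  structure(c(list(surface = surf), lrt,
              list(markers = markers, n = sum(ok))),
            class = "pleiotropy_profile")
}

#' Parametric bootstrap p-value for the pleiotropy test
#'
#' Simulates `B` trait pairs from the fitted pleiotropic null (both traits
#' regressed on the dosages at the diagonal argmax, bivariate normal
#' residuals with the fitted covariance), recomputes the likelihood ratio
#' statistic for each, and reports the plus-one estimator
#' `p = (1 + #\{lrt_b >= lrt_obs\}) / (B + 1)`.  Replicates with a
#' non-finite statistic are counted as exceedances (conservative) and
#' reported, never silently dropped.
#'
#' @inheritParams bivariate_profile
#' @param B bootstrap replicates (>= 50; the reference analysis used 1000).
#' @param seed integer seed.
#' @return list of class `"pleio_boot"`: `lrt`, `p`, `B`,
#'   `n_nonconvergent`, `argmax`, `diag_argmax`, `markers`, `n`.
#' @export
bootstrap_pvalue <- function(y1, y2, dosage, markers, covariates = NULL,
                             B = 1000, seed = NULL, niter = 4) {
  if (B < 50) stop("B must be >= 50")
  prof <- bivariate_profile(y1, y2, dosage, markers, covariates, niter)
  ok <- complete.cases(y1, y2)
  parts <- pleio_parts(dosage, markers, covariates, which(ok))
  nn <- sum(ok)

  ## pleiotropic null at the diagonal argmax: identical regressors in both
  ## equations, so the SUR fit reduces to per-equation OLS (Kruskal)
  d_idx <- match(prof$diag_argmax, markers)
  pd <- parts$pd
  Xd <- cbind(parts$C, parts$D[, (d_idx - 1) * pd + seq_len(pd), drop = FALSE])
  f1 <- lm.fit(Xd, y1[ok])
  f2 <- lm.fit(Xd, y2[ok])
  mu <- cbind(y1[ok] - f1$residuals, y2[ok] - f2$residuals)
  R <- cbind(f1$residuals, f2$residuals)
  Sigma <- crossprod(R) / nn
  L <- chol(Sigma + diag(1e-12 * mean(diag(Sigma)), 2))

  with_seed(seed, {
    lrt_b <- numeric(B)
    for (b in seq_len(B)) {
      Yb <- mu + matrix(rnorm(2 * nn), nn, 2) %*% L
      surf <- pleio_surface(parts, Yb, niter)
      lrt_b[b] <- surface_lrt(surf)$lrt
    }
    bad <- !is.finite(lrt_b)
    exceed <- sum(lrt_b[!bad] >= prof$lrt) + sum(bad)
    structure(list(lrt = prof$lrt, p = (1 + exceed) / (B + 1), B = B,
                   n_nonconvergent = sum(bad), argmax = prof$argmax,
                   diag_argmax = prof$diag_argmax, markers = markers,
                   n = nn),
              class = "pleio_boot")
  })
}

## fixed (Y-independent) pieces: design blocks and their cross-products
pleio_parts <- function(dosage, markers, covariates, rows) {
  n_all <- length(dosage$individuals)
  C <- scan_design(covariates, n_all)[rows, , drop = FALSE]
  k <- length(markers)
  pd <- 7                               # 8 founders, one dropped vs intercept
  arr <- dosage$dosage[rows, markers, 1:7, drop = FALSE]
  D <- matrix(aperm(arr, c(1, 3, 2)), nrow = length(rows))  # marker-major
  list(C = C, D = D, k = k, pd = pd, n = length(rows),
       CtC = crossprod(C), CtD = crossprod(C, D), DtD = crossprod(D))
}

pleio_surface <- function(parts, Y, niter) {
  pleio_grid_cpp(parts$CtC, parts$CtD, parts$DtD,
                 crossprod(parts$C, Y), crossprod(parts$D, Y),
                 crossprod(Y), parts$n, parts$k, parts$pd, niter)
}

surface_lrt <- function(surf) {
  k <- nrow(surf)
  dg <- diag(surf)
  i_dg <- which.max(dg)
  mx <- which(surf == max(surf, na.rm = TRUE), arr.ind = TRUE)[1, ]
  lrt <- max(0, max(surf, na.rm = TRUE) - max(dg, na.rm = TRUE))
  list(lrt = lrt,
       argmax = c(rownames(surf)[mx[1]], colnames(surf)[mx[2]]),
       diag_argmax = rownames(surf)[i_dg])
}

#' Markers spanning an interval for the pleiotropy scan
#'
#' Convenience selector: markers of one chromosome within
#' `[lo_cM - pad_cM, hi_cM + pad_cM]`.
#'
#' @param map a `genetic_map`.
#' @param chr chromosome label.
#' @param lo_cM,hi_cM interval bounds in cM.
#' @param pad_cM padding (default 2 cM).
#' @return character vector of marker ids.
#' @export
interval_markers <- function(map, chr, lo_cM, hi_cM, pad_cM = 2) {
  sel <- map$chr == chr & map$pos_cM >= lo_cM - pad_cM &
    map$pos_cM <= hi_cM + pad_cM
  map$marker[sel]
}
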