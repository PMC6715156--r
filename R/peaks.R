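#' Bayes credible support interval for a QTL
#'
#' The posterior over the marker grid of one chromosome is proportional to
#' `10^LOD`.  The interval is the smallest contiguous span containing the
#' peak whose posterior mass reaches `prob`, grown symmetrically outward
#' from the peak one marker per side at a time (clipped at the chromosome
#' ends).
#'
#' @param lod LOD values over one chromosome's markers (>= 2, finite).
#' @param pos optional positions (same length) used for the reported
#'   bounds; defaults to marker indices.
#' @param prob target posterior mass (default 0.95).
#' @return list: `lo`, `hi` (indices), `ci_lo`, `ci_hi` (positions),
#'   `coverage` (attained mass).
#' @export
bayes_interval <- function(lod, pos = NULL, prob = 0.95) {
  if (length(lod) < 2) stop("need >= 2 markers on the chromosome")
  if (any(!is.finite(lod))) stop("non-finite LOD values")
  if (is.null(pos)) pos <- seq_along(lod)
  w <- 10^(lod - max(lod))
  w <- w / sum(w)
  peak <- which.max(lod)
  lo <- hi <- peak
  mass <- w[peak]
  while (mass < prob && (lo > 1 || hi < length(lod))) {
    lo <- max(1L, lo - 1L)
    hi <- min(length(lod), hi + 1L)
    mass <- sum(w[lo:hi])
  }
  list(lo = lo, hi = hi, ci_lo = pos[lo], ci_hi = pos[hi], coverage = mass)
}

#' Call QTL peaks from a genome scan
#'
#' Local maxima at or above `threshold` are reported per chromosome; maxima
#' closer than `min_peak_separation_cM` are merged keeping the higher LOD.
#' Each peak carries its Bayes credible interval and, when the phenotype
#' and dosages are supplied, the eight sum-to-zero founder allele effects.
#'
#' @param scan a `scan_result` from [genome_scan()].
#' @param threshold LOD calling threshold (> 0).
#' @param min_peak_separation_cM merge window (default 10 cM).
#' @param prob credible-interval mass (default 0.95).
#' @param y,dosage,covariates,kinship optional; when given, founder
#'   coefficients are estimated at each peak via [founder_effects()].
#' @param shrink ridge shrinkage passed to [founder_effects()].
#' @return data frame of class `"qtl_peaks"`: `chr`, `pos_Mbp`, `pos_cM`,
#'   `lod`, `ci_lo`, `ci_hi`, `coef_A` .. `coef_H`.  Zero rows when no peak
#'   clears the threshold.
#' @export
find_peaks <- function(scan, threshold, min_peak_separation_cM = 10,
                       prob = 0.95, y = NULL, dosage = NULL,
                       covariates = NULL, kinship = NULL, shrink = 0) {
  if (threshold <= 0) stop("threshold must be positive")
  rows <- list()
  for (ch in unique(scan$chr)) {
    sc <- scan[scan$chr == ch, ]
    lod <- sc$lod
    m <- length(lod)
    is_max <- vapply(seq_len(m), function(i) {
      lod[i] >= threshold &&
        (i == 1 || lod[i] >= lod[i - 1]) &&
        (i == m || lod[i] >= lod[i + 1])
    }, logical(1))
    cand <- which(is_max)
    if (!length(cand)) next
    cand <- cand[order(-lod[cand])]
    kept <- integer(0)
    for (i in cand) {
      if (!length(kept) ||
          all(abs(sc$pos_cM[kept] - sc$pos_cM[i]) >= min_peak_separation_cM))
        kept <- c(kept, i)
    }
    for (i in sort(kept)) {
      ci <- bayes_interval(lod, sc$pos_Mbp, prob)
      ## interval recomputed around this peak when several peaks coexist
      if (which.max(lod) != i) {
        ci <- local_interval(lod, sc$pos_Mbp, i, prob)
      }
      coefs <- rep(NA_real_, 8)
      if (!is.null(y) && !is.null(dosage)) {
        coefs <- tryCatch(
          founder_effects(y, dosage, sc$marker[i], covariates, kinship,
                          shrink = shrink),
          error = function(e) rep(NA_real_, 8))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        marker = sc$marker[i], chr = ch, pos_Mbp = sc$pos_Mbp[i],
        pos_cM = sc$pos_cM[i], lod = lod[i],
        ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
        t(setNames(coefs, paste0("coef_", LETTERS[1:8]))),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(0), chr = character(0),
               pos_Mbp = numeric(0), pos_cM = numeric(0), lod = numeric(0),
               ci_lo = numeric(0), ci_hi = numeric(0),
               matrix(numeric(0), 0, 8,
                      dimnames = list(NULL, paste0("coef_", LETTERS[1:8]))),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("qtl_peaks", "data.frame")
  out
}

## interval grown around a secondary peak rather than the global maximum
local_interval <- function(lod, pos, peak, prob) {
  w <- 10^(lod - max(lod))
  w <- w / sum(w)
  lo <- hi <- peak
  mass <- w[peak]
  while (mass < prob && (lo > 1 || hi < length(lod))) {
    lo <- max(1L, lo - 1L)
    hi <- min(length(lod), hi + 1L)
    mass <- sum(w[lo:hi])
  }
  list(lo = lo, hi = hi, ci_lo = pos[lo], ci_hi = pos[hi], coverage = mass)
}

#' Founder allele effects at a marker
#'
#' Sum-to-zero constrained founder coefficients from the (generalized)
#' least squares fit of the phenotype on the eight founder dosages plus
#' covariates, with optional ridge shrinkage of the founder block toward
#' zero for display stability.
#'
#' @param y phenotype vector aligned with `dosage$individuals`.
#' @param dosage a `founder_dosage` object.
#' @param marker marker id at which to estimate effects.
#' @param covariates optional covariate data frame.
#' @param kinship optional `kinship_set`; the marker's LOCO matrix supplies
#'   GLS weights via the null-model `h2`.
#' @param shrink ridge penalty (>= 0) on the founder coefficients.
#' @return named numeric 8-vector (`A` .. `H`), summing to zero.
#' @export
founder_effects <- function(y, dosage, marker, covariates = NULL,
                            kinship = NULL, shrink = 0) {
  map <- dosage$map
  if (!marker %in% map$marker) stop("marker '", marker, "' not in map")
  ok <- !is.na(y)
  if (sum(ok) < 10) stop("too few complete observations")
  if (!all(ok)) {
    dosage <- subset_dosage(dosage, which(ok))
    covariates <- if (!is.null(covariates)) covariates[ok, , drop = FALSE]
    kinship <- subset_kinship(kinship, which(ok))
    y <- y[ok]
  }
  n <- length(y)
  X0 <- scan_design(covariates, n)
  D <- dosage$dosage[, marker, ]
  if (!is.null(kinship)) {
    ch <- map$chr[map$marker == marker]
    e <- eigen_kinship(kinship$loco[[ch]])
    yr <- drop(crossprod(e$U, y))
    X0r <- crossprod(e$U, X0)
    h2 <- reml_h2(yr, X0r, e$d)$h2
    sw <- 1 / sqrt(h2 * e$d + 1 - h2)
    yw <- yr * sw
    Xw <- cbind(X0r, crossprod(e$U, D[, 1:7])) * sw
  } else {
    yw <- y
    Xw <- cbind(X0, D[, 1:7])
  }
  p0 <- ncol(X0)
  if (shrink > 0) {
    A <- crossprod(Xw) + diag(c(rep(0, p0), rep(shrink, 7)))
    b <- solve(A, crossprod(Xw, yw))
  } else {
    qx <- qr(Xw)
    if (qx$rank < ncol(Xw))
      stop("collinear dosage columns at marker ", marker,
           " (consider shrink > 0)")
    b <- qr.coef(qx, yw)
  }
  coef8 <- c(b[(p0 + 1):(p0 + 7)], 0)
  coef8 <- coef8 - mean(coef8)
  setNames(as.numeric(coef8), LETTERS[1:8])
}
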