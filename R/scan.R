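#' Haplotype-regression genome scan
#'
#' At every marker the phenotype is regressed on the eight founder
#' haplotype dosages together with additive covariates; the reported
#' statistic is `LOD = (n/2) log10(RSS0 / RSS1)`.  With a kinship set, the
#' variance ratio `h2` is estimated once per chromosome under the null
#' (LOCO matrix of that chromosome) and the per-marker fits are generalized
#' least squares with the corresponding weights.  With `kinship = NULL` the
#' scan is ordinary (Haley-Knott style) regression.
#'
#' Missing phenotype values are dropped trait-wise (complete-case).
#' Identifiability at a marker comes from dropping one founder column in
#' the fit; reported founder effects (see [founder_effects()]) use the
#' sum-to-zero parameterization.
#'
#' @param y numeric phenotype vector, aligned with `dosage$individuals`
#'   (names checked when present).
#' @param dosage a `founder_dosage` object.
#' @param covariates optional covariate data frame (columns other than `id`
#'   enter as additive fixed effects; factors are dummy-coded).
#' @param kinship a `kinship_set` from [compute_kinship_loco()], or `NULL`.
#' @param prep optional precomputed [scan_prep()] object (rotations reused
#'   across traits and permutations).
#' @return data frame of class `"scan_result"`: `marker`, `chr`, `pos_cM`,
#'   `pos_Mbp`, `lod`, with attributes `h2` (per chromosome), `n`.
#' @export
genome_scan <- function(y, dosage, covariates = NULL, kinship = NULL,
                        prep = NULL) {
  stopifnot(inherits(dosage, "founder_dosage"))
  if (!is.null(names(y)) &&
      !identical(unname(names(y)), unname(dosage$individuals)))
    stop("misaligned individual ids between phenotype and dosage")
  if (length(y) != length(dosage$individuals))
    stop("phenotype length does not match dosage")
  ok <- !is.na(y)
  if (!any(ok)) stop("all-missing trait")
  if (!all(ok)) {                     # complete-case subset, fresh prep
    dosage <- subset_dosage(dosage, which(ok))
    covariates <- if (!is.null(covariates)) covariates[ok, , drop = FALSE]
    kinship <- subset_kinship(kinship, which(ok))
    y <- y[ok]
    prep <- NULL
  }
  if (is.null(prep)) prep <- scan_prep(dosage, covariates, kinship)
  eng <- scan_engine(prep, y)
  out <- data.frame(marker = prep$map$marker, chr = prep$map$chr,
                    pos_cM = prep$map$pos_cM, pos_Mbp = prep$map$pos_Mbp,
                    lod = eng$lod, stringsAsFactors = FALSE)
  attr(out, "h2") <- eng$h2
  attr(out, "n") <- length(y)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Precompute scan rotations for reuse across traits/permutations
#'
#' Eigendecomposes each LOCO kinship matrix once and stores the rotated
#' covariate design and rotated dosage columns, so repeated scans (many
#' traits, permutations, bootstrap replicates) only rotate the phenotype.
#'
#' @inheritParams genome_scan
#' @return opaque list consumed by [genome_scan()] and
#'   [permutation_thresholds()].
#' @export
scan_prep <- function(dosage, covariates = NULL, kinship = NULL) {
  map <- dosage$map
  n <- length(dosage$individuals)
  X0 <- scan_design(covariates, n)
  if (qr(X0)$rank < ncol(X0)) stop("covariate design is rank deficient")
  chrs <- unique(map$chr)
  per_chr <- list()
  for (ch in chrs) {
    idx <- which(map$chr == ch)
    D <- matrix(dosage$dosage[, idx, 1:7], nrow = n)  # n x (m*7), founder-major
    if (!is.null(kinship)) {
      K <- kinship$loco[[ch]]
      if (is.null(K)) stop("kinship set lacks chromosome ", ch)
      e <- eigen_kinship(K)
      per_chr[[ch]] <- list(U = e$U, d = e$d,
                            X0r = crossprod(e$U, X0),
                            Dr = crossprod(e$U, D), idx = idx)
    } else {
      per_chr[[ch]] <- list(U = NULL, d = NULL, X0r = X0, Dr = D, idx = idx)
    }
  }
  list(map = map, n = n, X0 = X0, chrs = chrs, per_chr = per_chr)
}

## core scan: returns lod vector over all markers plus per-chr h2
scan_engine <- function(prep, y, perm = NULL) {
  n <- prep$n
  lod <- numeric(nrow(prep$map))
  h2s <- setNames(numeric(length(prep$chrs)), prep$chrs)
  X0v <- if (is.null(perm)) prep$X0 else prep$X0[perm, , drop = FALSE]
  yv <- if (is.null(perm)) y else y[perm]
  for (ch in prep$chrs) {
    pc <- prep$per_chr[[ch]]
    m <- length(pc$idx)
    if (is.null(pc$U)) {
      yr <- yv; X0r <- X0v; sw <- rep(1, n); h2 <- 0
    } else {
      yr <- drop(crossprod(pc$U, yv))
      X0r <- if (is.null(perm)) pc$X0r else crossprod(pc$U, X0v)
      ols_rss <- sum(qr.resid(qr(X0r), yr)^2)
      if (ols_rss < 1e-12 * max(1, sum(yr^2))) {  # trait fully explained
        lod[pc$idx] <- 0
        h2s[ch] <- 0
        next
      }
      h2 <- reml_h2(yr, X0r, pc$d)$h2
      sw <- 1 / sqrt(h2 * pc$d + 1 - h2)
    }
    h2s[ch] <- h2
    Xw <- X0r * sw
    yw <- yr * sw
    rss0 <- sum(qr.resid(qr(Xw), yw)^2)
    if (rss0 < 1e-12 * max(1, sum(yw^2))) {     # constant/fully explained
      lod[pc$idx] <- 0
      next
    }
    Dw <- pc$Dr * sw
    lods <- numeric(m)
    for (k in seq_len(m)) {
      cols <- k + (0:6) * m
      f <- .lm.fit(cbind(Xw, Dw[, cols, drop = FALSE]), yw)
      lods[k] <- (n / 2) * log10(rss0 / sum(f$residuals^2))
    }
    lod[pc$idx] <- pmax(lods, 0)
  }
  list(lod = lod, h2 = h2s)
}

## covariate design with intercept; factors dummy-coded (fixed effects)
scan_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  stopifnot(nrow(covariates) == n)
  cols <- setdiff(names(covariates), "id")
  if (!length(cols)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  X <- model.matrix(~ ., data = covariates[, cols, drop = FALSE])
  colnames(X)[1] <- "intercept"
  X
}

subset_dosage <- function(dosage, rows) {
  dosage$dosage <- dosage$dosage[rows, , , drop = FALSE]
  dosage$individuals <- dosage$individuals[rows]
  dosage
}

subset_kinship <- function(kinship, rows) {
  if (is.null(kinship)) return(NULL)
  kinship$loco <- lapply(kinship$loco, function(K) K[rows, rows, drop = FALSE])
  kinship$overall <- kinship$overall[rows, rows, drop = FALSE]
  kinship
}

#' Genome-wide significance thresholds by permutation
#'
#' Each permutation shuffles the rows of the phenotype together with the
#' covariates against the genotypes (preserving trait-covariate
#' association), rescans the genome, and records the genome-wide maximum
#' LOD.  With `pooled = TRUE` (the default, matching the study's pooled
#' thresholds) `n_perm` is the total number of permutation maxima,
#' distributed as evenly as possible across the supplied traits, and a
#' single threshold per `alpha` is the `1 - alpha` quantile of the pooled
#' maxima.  With `pooled = FALSE` each trait receives `n_perm` permutations
#' and per-trait thresholds are returned.
#'
#' @param traits data frame or matrix of phenotypes (an `id` column is
#'   ignored), individuals in rows.
#' @param dosage,covariates,kinship as in [genome_scan()].
#' @param n_perm number of permutations (>= 10; >= 100 recommended).
#' @param alphas genome-wide error rates, each in (0, 1).
#' @param pooled pool permutation maxima across traits (default TRUE).
#' @param seed integer seed.
#' @return list of class `"threshold_set"`: `thresholds` (named vector, or
#'   alpha x trait matrix when `pooled = FALSE`), `alphas`, `n_perm`,
#'   `pooled`, `max_lods`.
#' @export
permutation_thresholds <- function(traits, dosage, covariates = NULL,
                                   kinship = NULL, n_perm = 1000,
                                   alphas = c(0.05, 0.2, 0.5),
                                   pooled = TRUE, seed = NULL) {
  if (n_perm < 10) stop("n_perm must be >= 10")
  if (any(alphas <= 0 | alphas >= 1)) stop("alphas must lie in (0, 1)")
  Y <- count_matrix(traits)
  n <- nrow(Y)
  stopifnot(n == length(dosage$individuals))
  prep <- scan_prep(dosage, covariates, kinship)
  n_tr <- ncol(Y)
  counts <- if (pooled) {
    base <- n_perm %/% n_tr
    extra <- n_perm %% n_tr
    base + (seq_len(n_tr) <= extra)
  } else rep(n_perm, n_tr)

  with_seed(seed, {
    maxlods <- vector("list", n_tr)
    for (j in seq_len(n_tr)) {
      yj <- Y[, j]
      if (anyNA(yj)) stop("permutation thresholds require complete traits; ",
                          "drop or impute missing values first")
      ml <- numeric(counts[j])
      for (b in seq_len(counts[j])) {
        perm <- sample.int(n)
        ml[b] <- max(scan_engine(prep, yj, perm = perm)$lod)
      }
      maxlods[[j]] <- ml
    }
    if (pooled) {
      pool <- unlist(maxlods)
      thr <- setNames(quantile(pool, 1 - alphas, names = FALSE, type = 7),
                      as.character(alphas))
      structure(list(thresholds = thr, alphas = alphas, n_perm = n_perm,
                     pooled = TRUE, max_lods = pool),
                class = "threshold_set")
    } else {
      thr <- vapply(maxlods, function(ml)
        quantile(ml, 1 - alphas, names = FALSE, type = 7), numeric(length(alphas)))
      thr <- matrix(thr, nrow = length(alphas),
                    dimnames = list(as.character(alphas), colnames(Y)))
      structure(list(thresholds = thr, alphas = alphas, n_perm = n_perm,
                     pooled = FALSE, max_lods = maxlods),
                class = "threshold_set")
    }
  })
}
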