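#' Co-mapping QTL pairs between two peak sets
#'
#' Pairs of peaks (one from each set) on the same chromosome whose closed
#' support intervals intersect and whose LODs both meet the relaxed
#' co-mapping threshold (default LOD 6.1, the study's P < 0.5 level).
#' Touching endpoints count as overlap: support intervals are approximate,
#' so the rule is deliberately generous.
#'
#' @param peaks_a,peaks_b `qtl_peaks` data frames (e.g. microbial and
#'   metabolite peak sets) carrying `ci_lo`/`ci_hi` support intervals.
#' @param lod_min relaxed LOD threshold applied to both peaks (default 6.1).
#' @return data frame: `trait_a`, `trait_b` (taken from a `trait` column
#'   when present, else the peak marker), `chr`, `overlap_lo`, `overlap_hi`,
#'   `lod_a`, `lod_b`, `r_effects` (Pearson correlation of the two founder
#'   coefficient vectors, `NA` when coefficients are absent).
#' @export
find_overlaps <- function(peaks_a, peaks_b, lod_min = 6.1) {
  rows <- list()
  lab <- function(p, i) {
    if ("trait" %in% names(p)) p$trait[i] else p$marker[i]
  }
  for (i in seq_len(nrow(peaks_a))) {
    if (peaks_a$lod[i] < lod_min) next
    for (j in seq_len(nrow(peaks_b))) {
      if (peaks_b$lod[j] < lod_min) next
      if (peaks_a$chr[i] != peaks_b$chr[j]) next
      lo <- max(peaks_a$ci_lo[i], peaks_b$ci_lo[j])
      hi <- min(peaks_a$ci_hi[i], peaks_b$ci_hi[j])
      if (lo > hi) next                         # closed-interval overlap
      ca <- as.numeric(peaks_a[i, paste0("coef_", LETTERS[1:8])])
      cb <- as.numeric(peaks_b[j, paste0("coef_", LETTERS[1:8])])
      r <- if (anyNA(ca) || anyNA(cb)) NA_real_ else
        allele_effect_similarity(ca, cb)
      rows[[length(rows) + 1L]] <- data.frame(
        trait_a = lab(peaks_a, i), trait_b = lab(peaks_b, j),
        chr = peaks_a$chr[i], overlap_lo = lo, overlap_hi = hi,
        lod_a = peaks_a$lod[i], lod_b = peaks_b$lod[j],
        r_effects = r, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait_a = character(0), trait_b = character(0),
               chr = character(0), overlap_lo = numeric(0),
               overlap_hi = numeric(0), lod_a = numeric(0),
               lod_b = numeric(0), r_effects = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Similarity of founder allele-effect patterns
#'
#' Pearson correlation of two 8-vectors of founder coefficients.  The sign
#' is preserved, so traits driven in opposite directions by the same
#' founders (e.g. an allele raising one trait and lowering the other) score
#' -1 rather than +1.
#'
#' @param coefs_a,coefs_b numeric 8-vectors.
#' @return correlation in `[-1, 1]`.
#' @export
allele_effect_similarity <- function(coefs_a, coefs_b) {
  stopifnot(length(coefs_a) == 8, length(coefs_b) == 8)
  if (sd(coefs_a) == 0 || sd(coefs_b) == 0)
    stop("zero-variance coefficient vector: similarity undefined")
  cor(coefs_a, coefs_b)
}

#' Spearman correlation screen with Benjamini-Hochberg correction
#'
#' All trait pairs between (or within) two trait tables are tested by
#' Spearman's rank correlation (average ranks, pairwise-complete
#' observations); p-values are adjusted by the BH step-up procedure over
#' every tested pair, and pairs passing both the FDR and the absolute
#' correlation cutoffs are flagged.  Defaults mirror the study's screen
#' (FDR < 0.01, |rho| > 0.35).
#'
#' @param traits_a data frame/matrix of traits (columns; `id` column
#'   ignored).
#' @param traits_b optional second table; when `NULL`, all within-table
#'   pairs of `traits_a` are tested.
#' @param q_cutoff BH-adjusted significance cutoff (default 0.01).
#' @param abs_rho_cutoff absolute correlation cutoff (default 0.35).
#' @return data frame: `trait_a`, `trait_b`, `rho`, `p`, `q`, `pass`.
#'   Constant traits are excluded with a warning.
#' @export
spearman_bh_screen <- function(traits_a, traits_b = NULL, q_cutoff = 0.01,
                               abs_rho_cutoff = 0.35) {
  A <- count_matrix(traits_a)
  B <- if (is.null(traits_b)) NULL else count_matrix(traits_b)
  drop_const <- function(M) {
    const <- apply(M, 2, function(x) {
      x <- x[!is.na(x)]
      length(x) < 3 || max(x) - min(x) == 0
    })
    if (any(const))
      warning("excluding constant/short trait(s): ",
              paste(colnames(M)[const], collapse = ", "))
    M[, !const, drop = FALSE]
  }
  A <- drop_const(A)
  if (!is.null(B)) B <- drop_const(B)
  pairs <- if (is.null(B)) {
    cn <- colnames(A)
    if (length(cn) < 2) stop("need >= 2 traits for a within-table screen")
    t(utils::combn(cn, 2))
  } else {
    as.matrix(expand.grid(colnames(A), colnames(B),
                          stringsAsFactors = FALSE))
  }
  res <- apply(pairs, 1, function(pr) {
    x <- A[, pr[1]]
    y <- if (is.null(B)) A[, pr[2]] else B[, pr[2]]
    ok <- complete.cases(x, y)
    if (sum(ok) < 3) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                    exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  })
  out <- data.frame(trait_a = pairs[, 1], trait_b = pairs[, 2],
                    rho = res[1, ], p = res[2, ], stringsAsFactors = FALSE)
  out$q <- p.adjust(out$p, method = "BH")
  out$pass <- !is.na(out$q) & out$q < q_cutoff &
    abs(out$rho) > abs_rho_cutoff
  attr(out, "settings") <- list(q_cutoff = q_cutoff,
                                abs_rho_cutoff = abs_rho_cutoff)
  rownames(out) <- NULL
  out
}
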