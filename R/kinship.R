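#' Kinship from founder haplotype dosages
#'
#' Genetic similarity `K_ij = (1/M) * sum_m sum_f (d_imf/2)(d_jmf/2)`, the
#' mean over markers of the inner product of haplotype-probability vectors.
#' Diagonal entries lie in (0, 1] (1 at fully homozygous hard mosaics).
#'
#' @param dosage a `founder_dosage` object.
#' @param markers optional marker subset (default: all markers).
#' @return symmetric individuals x individuals matrix.
#' @export
compute_kinship <- function(dosage, markers = NULL) {
  d <- dosage$dosage
  if (!is.null(markers)) d <- d[, markers, , drop = FALSE]
  n <- dim(d)[1]
  P <- matrix(d / 2, nrow = n)          # n x (m*8), founder-within-marker
  K <- tcrossprod(P) / dim(d)[2]
  dimnames(K) <- list(dimnames(d)[[1]], dimnames(d)[[1]])
  (K + t(K)) / 2
}

#' Leave-one-chromosome-out (LOCO) kinship matrices
#'
#' One kinship matrix per chromosome, computed from all markers NOT on that
#' chromosome, so the polygenic term of a scan never absorbs the signal of
#' the scanned chromosome.
#'
#' @param dosage a `founder_dosage` object covering >= 2 chromosomes.
#' @return list of class `"kinship_set"`: `loco` (named list of matrices,
#'   one per chromosome), `overall`, `method = "loco"`.
#' @export
compute_kinship_loco <- function(dosage) {
  map <- dosage$map
  chrs <- unique(map$chr)
  if (length(chrs) < 2)
    stop("LOCO kinship needs >= 2 chromosomes; use compute_kinship() for a ",
         "single-chromosome (non-LOCO) analysis")
  d <- dosage$dosage
  n <- dim(d)[1]
  m_all <- dim(d)[2]
  P <- matrix(d / 2, nrow = n)
  S_all <- tcrossprod(P)
  loco <- list()
  for (ch in chrs) {
    idx <- which(map$chr == ch)
    cols <- as.vector(outer(idx, (seq_len(8) - 1) * m_all, "+"))
    Pc <- P[, cols, drop = FALSE]
    Kc <- (S_all - tcrossprod(Pc)) / (m_all - length(idx))
    dimnames(Kc) <- list(dimnames(d)[[1]], dimnames(d)[[1]])
    loco[[ch]] <- (Kc + t(Kc)) / 2
  }
  structure(list(loco = loco, overall = S_all / m_all, method = "loco"),
            class = "kinship_set")
}
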