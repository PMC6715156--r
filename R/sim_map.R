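#' Simulate an evenly spaced genetic/physical marker map
#'
#' Builds a pseudomarker grid of the kind used for multiparent genome
#' scans: markers evenly spaced in centimorgans within each autosome, with
#' physical positions obtained by dividing by a constant recombination
#' density.  Autosome labels are `"1".."n_chromosomes"`.
#'
#' @param n_chromosomes number of autosomes (mouse autosomes: 19).
#' @param markers_per_chr markers per chromosome (>= 2); ignored when
#'   `spacing_cM` is given.
#' @param chr_length_cM chromosome length in centimorgans (> 0).
#' @param cM_per_Mbp recombination density used to convert cM to Mbp.
#' @param spacing_cM optional grid spacing in cM; when supplied the marker
#'   count per chromosome is `chr_length_cM / spacing_cM + 1`.
#' @return A data frame of class `"genetic_map"` with columns `marker`,
#'   `chr`, `pos_cM`, `pos_Mbp`, strictly increasing within chromosome.
#' @examples
#' simulate_map(1, 6, 100, 2)
#' @export
simulate_map <- function(n_chromosomes = 19, markers_per_chr = 50,
                         chr_length_cM = 90, cM_per_Mbp = 2,
                         spacing_cM = NULL) {
  if (n_chromosomes < 1) stop("need at least one chromosome")
  if (chr_length_cM <= 0) stop("chr_length_cM must be positive")
  if (cM_per_Mbp <= 0) stop("cM_per_Mbp must be positive")
  if (!is.null(spacing_cM)) {
    if (spacing_cM <= 0) stop("spacing_cM must be positive")
    markers_per_chr <- round(chr_length_cM / spacing_cM) + 1L
  }
  if (markers_per_chr < 2) stop("need >= 2 markers per chromosome")

  per_chr <- lapply(seq_len(n_chromosomes), function(ch) {
    cm <- seq(0, chr_length_cM, length.out = markers_per_chr)
    data.frame(
      marker  = sprintf("c%d_m%04d", ch, seq_len(markers_per_chr)),
      chr     = as.character(ch),
      pos_cM  = cm,
      pos_Mbp = cm / cM_per_Mbp,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, per_chr)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

validate_map <- function(map) {
  stopifnot(all(c("marker", "chr", "pos_cM", "pos_Mbp") %in% names(map)))
  if (anyDuplicated(map$marker)) stop("marker ids must be unique")
  for (ch in unique(map$chr)) {
    p <- map$pos_cM[map$chr == ch]
    if (any(diff(p) <= 0)) stop("pos_cM not strictly increasing on chr ", ch)
  }
  invisible(map)
}
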