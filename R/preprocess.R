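#' Core measurable microbiota prevalence filter
#'
#' Retains microbial features detected (count > 0) in at least
#' `min_prevalence` of individuals, the "core measurable microbiota"
#' criterion (default 20%).  The boundary is inclusive and feature order is
#' preserved; the filter is idempotent.
#'
#' @param counts individuals x features matrix or data frame of non-negative
#'   counts (feature columns; an `id` column is carried through untouched).
#' @param min_prevalence fraction in (0, 1]; default 0.2.
#' @return filtered table of the same type.
#' @export
cmm_filter <- function(counts, min_prevalence = 0.2) {
  if (min_prevalence <= 0 || min_prevalence > 1)
    stop("min_prevalence must be in (0, 1]")
  m <- count_matrix(counts)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty count table")
  prev <- colMeans(m > 0)
  keep <- colnames(m)[prev >= min_prevalence - 1e-12]
  subset_features(counts, keep)
}

#' Agglomerate counts to a higher taxonomic rank
#'
#' Features sharing the same lineage prefix through `rank` are summed.
#' Lineages are Greengenes-style strings
#' (`k__...;p__...;c__...;o__...;f__...;g__...;s__...`).  Features with an
#' empty or missing assignment at the requested rank are grouped under an
#' explicit `unclassified-<parent>` bucket.
#'
#' @param counts individuals x features count table; columns named by
#'   feature id.
#' @param taxonomy named character vector of lineage strings, names matching
#'   feature columns.
#' @param rank one of `"genus"`, `"family"`, `"order"`, `"class"`,
#'   `"phylum"`.
#' @return count table with one column per taxon at `rank`; column sums of
#'   the input are conserved.
#' @export
agglomerate <- function(counts, taxonomy,
                        rank = c("genus", "family", "order", "class",
                                 "phylum")) {
  rank <- match.arg(rank)
  m <- count_matrix(counts)
  feats <- colnames(m)
  if (!all(feats %in% names(taxonomy)))
    stop("taxonomy missing for feature(s): ",
         paste(setdiff(feats, names(taxonomy)), collapse = ", "))
  depth <- c(kingdom = 1, phylum = 2, class = 3, order = 4, family = 5,
             genus = 6)[[rank]]
  labels <- vapply(feats, function(f) {
    parts <- strsplit(taxonomy[[f]], ";")[[1]]
    parts <- trimws(parts)
    if (length(parts) > 7)
      stop("malformed lineage for feature ", f, " (> 7 ranks)")
    at <- if (length(parts) >= depth) parts[depth] else ""
    if (nchar(sub("^[a-z]__", "", at)) > 0) {
      paste(parts[seq_len(depth)], collapse = ";")
    } else {
      parent <- parts[nchar(sub("^[a-z]__", "", parts)) > 0]
      paste0("unclassified-", if (length(parent)) parent[length(parent)]
             else "root")
    }
  }, character(1))
  groups <- split(feats, labels)
  out <- vapply(groups, function(g) rowSums(m[, g, drop = FALSE]),
                numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), names(groups)))
  rebuild_table(counts, out)
}

#' Cumulative sum scaling normalization
#'
#' Per-sample scaling factor `s_j` is the sum of that sample's counts that
#' are at or below its `quantile_l` quantile of positive counts; normalized
#' values are `count / s_j * scale_constant`.  The normalization is
#' invariant to uniform scaling of a sample's counts.
#'
#' @param counts individuals x features count table.
#' @param quantile_l quantile in (0, 1) over each sample's positive counts
#'   (default 0.5).
#' @param scale_constant output scale (default 1000).
#' @return normalized table; attribute `transform` set to `"css"`.
#' @export
css_normalize <- function(counts, quantile_l = 0.5, scale_constant = 1000) {
  if (quantile_l <= 0 || quantile_l >= 1) stop("quantile_l must be in (0,1)")
  m <- count_matrix(counts)
  s <- vapply(seq_len(nrow(m)), function(j) {
    x <- m[j, ]
    pos <- x[x > 0]
    if (!length(pos))
      stop("sample '", rownames(m)[j] %||% j, "' has all-zero counts")
    q <- quantile(pos, quantile_l, type = 7, names = FALSE)
    sum(x[x <= q + 1e-12])
  }, numeric(1))
  out <- sweep(m, 1, s, "/") * scale_constant
  res <- rebuild_table(counts, out)
  attr(res, "transform") <- "css"
  res
}

#' Rank-based inverse normal transform
#'
#' Maps values to standard normal quantiles via
#' `qnorm((rank - c) / (n - 2c + 1))` with average ranks for ties (Blom
#' offset `c = 3/8` by default).  Missing values stay missing and do not
#' enter `n`.
#'
#' @param values numeric vector with >= 3 non-missing values.
#' @param offset_c rank offset; default 3/8.
#' @return transformed vector, monotone in the input.
#' @export
rank_inverse_normal <- function(values, offset_c = 3 / 8) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 3) stop("need >= 3 non-missing values")
  if (max(x) - min(x) == 0) stop("constant vector: rank transform undefined")
  r <- rank(x, ties.method = "average")
  n <- length(x)
  out <- values
  out[ok] <- qnorm((r - offset_c) / (n - 2 * offset_c + 1))
  out
}

#' Internal-standard normalization of metabolite peak areas
#'
#' Each sample's peak areas are divided by its internal-standard (d4-CDCA)
#' peak area and multiplied by the mean internal-standard area over samples:
#' `out = (area / IS_j) * mean(IS)`.  Zeros are preserved; when every IS
#' area is equal the transform is the identity.
#'
#' @param areas individuals x metabolites matrix or data frame of peak
#'   areas (an `id` column is carried through).
#' @param is_area numeric vector of internal-standard peak areas, one per
#'   sample, all > 0.
#' @return normalized table of the same type.
#' @export
internal_standard_normalize <- function(areas, is_area) {
  m <- count_matrix(areas)
  if (length(is_area) != nrow(m))
    stop("is_area must have one entry per sample")
  bad <- which(is_area <= 0)
  if (length(bad))
    stop("non-positive internal-standard area for sample(s): ",
         paste(rownames(m)[bad] %||% bad, collapse = ", "))
  out <- sweep(m, 1, is_area, "/") * mean(is_area)
  rebuild_table(areas, out)
}

#' Log2 transform of metabolite levels
#'
#' @param values numeric vector/matrix/data frame of non-negative values.
#' @param pseudo pseudo-count added before the log (default 0; peak areas
#'   are strictly positive after internal-standard normalization).
#' @return `log2(values + pseudo)`; attribute `transform` set to `"log2"`.
#' @export
log2_metabolites <- function(values, pseudo = 0) {
  if (is.data.frame(values) || is.matrix(values)) {
    m <- count_matrix(values)
    if (any(m < 0, na.rm = TRUE)) stop("negative input to log2 transform")
    res <- rebuild_table(values, log2(m + pseudo))
    attr(res, "transform") <- "log2"
    res
  } else {
    if (any(values < 0, na.rm = TRUE)) stop("negative input to log2 transform")
    log2(values + pseudo)
  }
}

## ---- small table helpers (id column in data frames is carried through) ----

count_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  df <- x
  idcol <- if ("id" %in% names(df)) "id" else NULL
  cols <- setdiff(names(df), idcol)
  m <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- if (!is.null(idcol)) df$id else rownames(df)
  m
}

rebuild_table <- function(orig, m) {
  if (is.matrix(orig)) return(m)
  out <- as.data.frame(m, check.names = FALSE, stringsAsFactors = FALSE)
  if ("id" %in% names(orig)) out <- cbind(id = orig$id, out)
  rownames(out) <- NULL
  out
}

subset_features <- function(orig, keep) {
  if (is.matrix(orig)) return(orig[, keep, drop = FALSE])
  cols <- if ("id" %in% names(orig)) c("id", keep) else keep
  orig[, cols, drop = FALSE]
}
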