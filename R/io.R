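#' Read and write the pipeline's delimited-text formats
#'
#' Maps are TSV with columns `marker`, `chr`, `pos_cM`, `pos_Mbp`.  Founder
#' dosages travel as long CSV (`individual`, `marker`, `founder`, `dosage`);
#' trait and covariate tables as CSV with a header row and the individual id
#' in the first column.
#'
#' @param map a `genetic_map`; `path` a file path.
#' @return readers return the corresponding object; writers return the path
#'   invisibly.
#' @name pleioscan-io
NULL

#' @rdname pleioscan-io
#' @param path file path.
#' @export
write_map_tsv <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pleioscan-io
#' @export
read_map_tsv <- function(path) {
  map <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chr = "character"))
  validate_map(map)
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @rdname pleioscan-io
#' @param dosage a `founder_dosage`.
#' @export
write_dosage_csv <- function(dosage, path) {
  d <- dosage$dosage
  long <- data.frame(
    individual = rep(dimnames(d)[[1]], times = dim(d)[2] * 8),
    marker = rep(rep(dimnames(d)[[2]], each = dim(d)[1]), times = 8),
    founder = rep(dimnames(d)[[3]], each = dim(d)[1] * dim(d)[2]),
    dosage = as.vector(d), stringsAsFactors = FALSE)
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pleioscan-io
#' @param map_path path to the matching map TSV.
#' @export
read_dosage_csv <- function(path, map_path) {
  map <- read_map_tsv(map_path)
  long <- read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(long$individual)
  founders <- LETTERS[1:8]
  d <- array(0, dim = c(length(ids), nrow(map), 8),
             dimnames = list(ids, map$marker, founders))
  d[cbind(match(long$individual, ids), match(long$marker, map$marker),
          match(long$founder, founders))] <- long$dosage
  structure(list(dosage = d, individuals = ids, founders = founders,
                 map = map), class = "founder_dosage")
}

#' Read a microbial count table from delimited text
#'
#' Accepts samples-in-rows (id in the first column) or features-in-rows
#' (feature id in the first column, samples in columns) layouts; by default
#' the orientation is detected from the first header field (`feature`,
#' `taxon`, `esv` or `otu` mean features in rows).
#'
#' @param path CSV or TSV file (delimiter inferred from the extension).
#' @param features_in_rows logical, or `NA` to autodetect.
#' @return data frame with `id` first and one column per feature.
#' @export
read_count_table <- function(path, features_in_rows = NA) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (is.na(features_in_rows))
    features_in_rows <- tolower(names(df)[1]) %in%
      c("feature", "feature_id", "taxon", "esv", "otu", "#otu id")
  if (features_in_rows) {
    feats <- df[[1]]
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    out <- data.frame(id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    names(out)[-1] <- feats
    rownames(out) <- NULL
    out
  } else {
    names(df)[1] <- "id"
    df
  }
}

#' Read a metabolite peak-area table with a declared internal standard
#'
#' @param path CSV with id in the first column and one column per
#'   metabolite, one of which is the internal-standard channel.
#' @param is_column internal-standard column name (default `"d4_CDCA"`).
#' @return list: `areas` (data frame without the IS column), `is_area`
#'   (numeric vector).
#' @export
read_metabolite_table <- function(path, is_column = "d4_CDCA") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "id"
  if (!is_column %in% names(df))
    stop("internal-standard column '", is_column, "' not found")
  list(areas = df[, setdiff(names(df), is_column), drop = FALSE],
       is_area = df[[is_column]])
}

#' Write a trait table with a sidecar JSON of per-trait transform state
#'
#' @param traits data frame, id in the first column.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @param classes,transforms named character vectors keyed by trait.
#' @export
write_trait_table <- function(traits, path, classes = NULL,
                              transforms = NULL) {
  write.csv(traits, path, row.names = FALSE)
  side <- list(classes = as.list(classes %||% character(0)),
               transforms = as.list(transforms %||% character(0)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
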