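# TSV readers and writers. Tab separation is deliberate: genus identifiers
# such as "Family_XIII_UCG-002" are unsafe in comma-separated files. UTF-8,
# missing values as empty cells.

#' Read a genus abundance table
#'
#' Expects a TSV whose first column holds sample IDs and whose remaining
#' columns are genera (integer or float cells).
#'
#' @param path file path.
#' @param kind abundance kind, default `"raw_counts"`.
#' @return a `composition_matrix`.
#' @export
read_abundance_tsv <- function(path, kind = "raw_counts") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("abundance table ", path, ": need a sample-ID column plus at ",
         "least one genus column", call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("abundance table ", path, ": duplicated sample IDs", call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(df[, -1L, drop = FALSE])[!vapply(df[, -1L, drop = FALSE],
                                                     is.numeric, logical(1))]
    stop("abundance table ", path, ": non-numeric genus column(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  rownames(m) <- ids
  composition_matrix(m, kind)
}

#' Write a composition matrix as TSV
#' @param x a `composition_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path) {
  m <- unclass_matrix(x)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a per-animal phenotype table
#'
#' TSV with a `sample_id` column and numeric trait columns (body weights,
#' intake, marker and fiber concentrations, degradation rates, ...).
#'
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @return data.frame.
#' @export
read_phenotype_tsv <- function(path, required = "sample_id") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("phenotype table ", path, ": missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("phenotype table ", path, ": duplicated sample IDs", call. = FALSE)
  }
  df
}

#' Read a genus -> phylum taxonomy table
#'
#' TSV with `genus` and `phylum` columns; an optional `lineage` column may
#' carry a semicolon-separated lineage string.
#'
#' @param path file path.
#' @return data.frame with at least `genus` and `phylum`.
#' @export
read_taxonomy_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(c("genus", "phylum"), colnames(df))
  if (length(missing)) {
    stop("taxonomy table ", path, ": missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}
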