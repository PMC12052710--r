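#' Samples-by-genera composition matrix
#'
#' A thin S3 wrapper around a numeric matrix of microbial abundances with an
#' explicit `kind` marking where the matrix sits in the preprocessing chain:
#' `"raw_counts"` (sequence counts), `"depth_normalized"` (counts rescaled to
#' a common depth), `"relative"` (rows closed to 1) or `"clr"` (centered
#' log-ratio coordinates, rows summing to 0).
#'
#' Rows are samples, columns are genera; both must be named so that sample
#' identity survives joins with phenotype tables.
#'
#' @param values numeric matrix, samples in rows and genera in columns.
#' @param kind one of `"raw_counts"`, `"depth_normalized"`, `"relative"`,
#'   `"clr"`.
#' @return A `composition_matrix`: the matrix with a `kind` attribute.
#' @examples
#' m <- matrix(c(5, 3, 0, 2, 8, 2), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
#' composition_matrix(m, "raw_counts")
#' @export
composition_matrix <- function(values,
                               kind = c("raw_counts", "depth_normalized",
                                        "relative", "clr")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x genera)", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have sample row names and genus column names",
         call. = FALSE)
  }
  if (anyNA(values)) stop("abundances must not contain NA", call. = FALSE)
  if (kind != "clr" && any(values < 0)) {
    stop("negative abundances are only allowed for kind = \"clr\"",
         call. = FALSE)
  }
  if (kind == "relative" && any(abs(rowSums(values) - 1) > 1e-9)) {
    stop("relative abundances must have rows summing to 1", call. = FALSE)
  }
  if (kind == "clr" && any(abs(rowSums(values)) > 1e-9)) {
    stop("clr rows must sum to 0", call. = FALSE)
  }
  structure(values, kind = kind, class = c("composition_matrix", "matrix"))
}

#' @export
print.composition_matrix <- function(x, ...) {
  cat(sprintf("composition_matrix [%s]: %d samples x %d genera\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  mat <- x
  attr(mat, "kind") <- NULL
  class(mat) <- "matrix"
  print(utils::head(mat[, seq_len(min(6L, ncol(mat))), drop = FALSE]), ...)
  invisible(x)
}

composition_kind <- function(x) {
  k <- attr(x, "kind")
  if (is.null(k)) stop("not a composition_matrix", call. = FALSE)
  k
}

as_composition <- function(x, kind) {
  composition_matrix(unclass_matrix(x), kind)
}

unclass_matrix <- function(x) {
  attr(x, "kind") <- NULL
  class(x) <- NULL
  as.matrix(x)
}
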