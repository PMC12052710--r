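#' Normalize counts to the minimum sequencing depth
#'
#' Rescales each sample's counts by `min(total) / total` so that every row
#' sums to the smallest library size in the table. Within-sample proportions
#' are preserved exactly; the operation is deterministic (no subsampling).
#' For a randomized rarefaction alternative see [rarefy_to_min_depth()].
#'
#' @param counts a `composition_matrix` of kind `"raw_counts"`.
#' @return a `composition_matrix` of kind `"depth_normalized"` whose row sums
#'   all equal the minimum input row sum.
#' @examples
#' m <- matrix(c(60, 40, 120, 80), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("g1", "g2")))
#' x <- normalize_to_min_depth(composition_matrix(m, "raw_counts"))
#' rowSums(x)  # both 100
#' @export
normalize_to_min_depth <- function(counts) {
  if (composition_kind(counts) != "raw_counts") {
    stop("`counts` must have kind \"raw_counts\"", call. = FALSE)
  }
  m <- unclass_matrix(counts)
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    stop("every sample must have a positive total count; empty sample(s): ",
         paste(rownames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  scaled <- m * (min(totals) / totals)
  composition_matrix(scaled, "depth_normalized")
}

#' Rarefy counts to the minimum sequencing depth
#'
#' Randomized alternative to [normalize_to_min_depth()]: subsamples each
#' sample's reads without replacement down to the smallest library size.
#'
#' @param counts a `composition_matrix` of kind `"raw_counts"` with integer
#'   cells.
#' @param seed integer seed for the subsampling RNG.
#' @return a `composition_matrix` of kind `"depth_normalized"`.
#' @export
rarefy_to_min_depth <- function(counts, seed = 1L) {
  if (composition_kind(counts) != "raw_counts") {
    stop("`counts` must have kind \"raw_counts\"", call. = FALSE)
  }
  m <- unclass_matrix(counts)
  totals <- rowSums(m)
  if (any(totals <= 0)) stop("empty sample(s) cannot be rarefied", call. = FALSE)
  depth <- min(totals)
  out <- with_seed(seed, {
    t(apply(m, 1L, function(row) {
      reads <- rep.int(seq_along(row), row)
      kept <- sample(reads, size = depth, replace = FALSE)
      tabulate(kept, nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(m)
  composition_matrix(out, "depth_normalized")
}

#' Per-genus sample prevalence
#'
#' Fraction of samples in which each genus has strictly positive abundance.
#' Prevalence routes genera between the binary and quantitative parts of the
#' two-part association model (see [route_genera()]); the conventional
#' boundary is 60%.
#'
#' @param x a `composition_matrix` of any kind except `"clr"` (CLR coordinates
#'   lose the zero structure).
#' @return named numeric vector in \[0, 1\], one entry per genus.
#' @examples
#' m <- matrix(c(1, 0, 2, 0, 3, 0), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("s", 1:3), c("g1", "g2")))
#' prevalence(composition_matrix(m, "raw_counts"))  # g1 = 1, g2 = 0
#' @export
prevalence <- function(x) {
  if (composition_kind(x) == "clr") {
    stop("prevalence is undefined on clr-transformed data", call. = FALSE)
  }
  colMeans(unclass_matrix(x) > 0)
}

#' Centered log-ratio transform
#'
#' Adds a pseudocount to every cell, closes each row to proportions, and maps
#' to CLR coordinates \eqn{\log(p_j / g(p))} where \eqn{g} is the row
#' geometric mean. CLR rows sum to zero, taking compositional abundances to an
#' unconstrained space suitable for correlation and regression.
#'
#' The pseudocount (default 0.5 on the depth-normalized count scale) handles
#' zeros; it is the only zero-replacement strategy used in this package.
#'
#' @param x a `composition_matrix` of kind `"raw_counts"` or
#'   `"depth_normalized"`.
#' @param pseudocount positive value added to every cell before closure.
#' @return a `composition_matrix` of kind `"clr"`.
#' @examples
#' m <- matrix(c(2, 1, 1), nrow = 1, dimnames = list("s1", c("a", "b", "c")))
#' clr_transform(composition_matrix(m, "raw_counts"), pseudocount = 1e-9)
#' @export
clr_transform <- function(x, pseudocount = 0.5) {
  kind <- composition_kind(x)
  if (!kind %in% c("raw_counts", "depth_normalized")) {
    stop("`x` must be raw or depth-normalized counts, not ", kind,
         call. = FALSE)
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      !is.finite(pseudocount) || pseudocount <= 0) {
    stop("`pseudocount` must be a single positive number", call. = FALSE)
  }
  m <- unclass_matrix(x) + pseudocount
  logm <- log(m)                       # closure cancels in the log ratio
  clr <- logm - rowMeans(logm)
  composition_matrix(clr, "clr")
}

#' Principal-component scores of a CLR matrix
#'
#' Column-centers the CLR matrix and projects it onto the top-`k` right
#' singular directions. The leading scores serve as covariates that absorb
#' community-level structure in the association model. Components are ordered
#' by decreasing explained variance; each component's sign is fixed so that
#' its largest-magnitude loading is positive.
#'
#' @param clr a `composition_matrix` of kind `"clr"`.
#' @param k number of components (default 3), must satisfy
#'   `k < min(n_samples, n_genera)`.
#' @return numeric matrix of scores, `n_samples` rows and `k` columns
#'   (`PC1..PCk`), with an attribute `"sdev"` carrying component standard
#'   deviations.
#' @export
principal_components <- function(clr, k = 3L) {
  if (composition_kind(clr) != "clr") {
    stop("`clr` must have kind \"clr\"", call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k <= 0L) stop("`k` must be a positive integer", call. = FALSE)
  m <- unclass_matrix(clr)
  if (k >= min(dim(m))) {
    stop("`k` must be smaller than both the sample and genus counts",
         call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry of each component is positive
  flip <- vapply(seq_len(k), function(j) {
    l <- load[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2L, flip, `*`)
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_len(k))
  attr(scores, "sdev") <- pc$sdev[seq_len(k)]
  scores
}
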