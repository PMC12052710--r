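#' Spearman rank correlation with small-sample exact p-value
#'
#' Computes rho as the Pearson correlation of mid-ranks (ties receive average
#' ranks). The two-sided p-value uses the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} for n above `exact_n`, and the
#' exact permutation distribution (all `n!` arrangements of one margin) for
#' small vectors, where the approximation is unreliable and enumeration is
#' cheap.
#'
#' Constant input leaves the correlation undefined; `rho` and `p` are then
#' returned as `NA` rather than raising an error, so screening loops can
#' carry the result forward.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact_n largest n for which the exact permutation p is used
#'   (default 9).
#' @return list with elements `rho`, `p` and `n`.
#' @examples
#' spearman_cor(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))$rho  # 0.8
#' @export
spearman_cor <- function(x, y, exact_n = 9L) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    perms <- all_permutations(n)
    # rho is affine in sum(rx * ry_perm); compute all n! values at once
    cross <- as.vector(matrix(ry[perms], nrow(perms)) %*% rx)
    rho_perm <- affine_rank_rho(rx, ry, cross)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# Map sums of cross products sum(rx_i * ry_perm_i) to correlations.
affine_rank_rho <- function(rx, ry, cross_sums) {
  n <- length(rx)
  sx <- sum(rx)
  sy <- sum(ry)
  denom <- sqrt((sum(rx^2) - sx^2 / n) * (sum(ry^2) - sy^2 / n))
  (cross_sums - sx * sy / n) / denom
}

#' Classify a correlation by the moderate/weak convention
#'
#' A correlation is `"moderate"` when p < 0.01 and |rho| > 0.40, `"weak"`
#' when p < 0.01 and 0.20 < |rho| <= 0.40, otherwise `"none"`. The boundary
#' |rho| = 0.40 is assigned to the weak class by default so that no
#' significant correlation above 0.20 is silently unclassified; set
#' `strict_bounds = TRUE` for literal strict inequalities on both sides
#' (|rho| = 0.40 then falls to `"none"`).
#'
#' @param rho,p numeric vectors (recycled to common length).
#' @param alpha significance threshold (default 0.01).
#' @param strict_bounds logical; see above.
#' @return character vector: `"moderate"`, `"weak"` or `"none"` (`"none"`
#'   for undefined correlations).
#' @examples
#' classify_correlation(c(0.45, 0.45, 0.30), c(0.005, 0.02, 0.005))
#' @export
classify_correlation <- function(rho, p, alpha = 0.01, strict_bounds = FALSE) {
  k <- max(length(rho), length(p))
  rho <- rep_len(rho, k)
  p <- rep_len(p, k)
  out <- rep("none", k)
  sig <- !is.na(rho) & !is.na(p) & p < alpha
  a <- abs(rho)
  upper_weak <- if (strict_bounds) sig & a < 0.40 else sig & a <= 0.40
  out[sig & a > 0.40] <- "moderate"
  out[upper_weak & a > 0.20] <- "weak"
  out
}

#' Spearman screen of a phenotype against every genus
#'
#' Correlates a phenotype with each genus column and classifies the
#' correlations; genera whose classification is not `"none"` form the
#' Spearman hit set of the three-method consensus.
#'
#' @param abundance a `composition_matrix` (any non-CLR kind; ranks are
#'   invariant to the depth scaling).
#' @param phenotype named numeric vector, names matching the sample rows.
#' @param target label for the phenotype (stored in the result).
#' @param alpha,strict_bounds passed to [classify_correlation()].
#' @return data.frame with one row per genus: `feature`, `target`, `method`,
#'   `statistic` (rho), `p`, `classification`.
#' @export
correlation_screen <- function(abundance, phenotype, target = "NDFD",
                               alpha = 0.01, strict_bounds = FALSE) {
  m <- unclass_matrix(abundance)
  phenotype <- match_samples(phenotype, rownames(m), "phenotype")
  res <- lapply(seq_len(ncol(m)), function(j) spearman_cor(m[, j], phenotype))
  rho <- vapply(res, `[[`, numeric(1), "rho")
  p <- vapply(res, `[[`, numeric(1), "p")
  data.frame(feature = colnames(m), target = target, method = "spearman",
             statistic = rho, p = p,
             classification = classify_correlation(rho, p, alpha,
                                                   strict_bounds),
             stringsAsFactors = FALSE)
}

# Align a named vector with the sample universe of a matrix; error listing
# offenders on mismatch.
match_samples <- function(v, samples, what) {
  if (is.null(names(v))) {
    if (length(v) != length(samples)) {
      stop("`", what, "` length does not match the sample count",
           call. = FALSE)
    }
    return(as.numeric(v))
  }
  missing <- setdiff(samples, names(v))
  if (length(missing)) {
    stop("`", what, "` is missing sample(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...", call. = FALSE)
  }
  as.numeric(v[samples])
}
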