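#' Single-pass outlier trimming at mean +/- k SD
#'
#' Computes the mean and sample SD (denominator n-1) once on the full vector
#' and keeps values inside `mean +/- k * SD`. The pass is deliberately not
#' iterated: one exclusion step precedes extreme-group construction.
#'
#' @param values numeric vector, length >= 3.
#' @param k SD multiplier (default 2).
#' @return logical keep mask, same length as `values`.
#' @examples
#' trim_outliers(c(rep(10, 9), 30))  # the 30 is dropped
#' @export
trim_outliers <- function(values, k = 2) {
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  if (anyNA(values)) stop("`values` must not contain NA", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  values >= m - k * s & values <= m + k * s
}

#' Extreme-phenotype group assignment
#'
#' After a single mean +/- `sd_multiplier` SD trimming pass, ranks the
#' phenotype in descending order and assigns the top `n` samples to the high
#' group and the bottom `n` to the low group. Ties straddling either cut are
#' resolved deterministically by sample ID order.
#'
#' @param values named numeric phenotype vector (names are sample IDs).
#' @param n group size (default 10).
#' @param sd_multiplier trimming multiplier (default 2); `Inf` disables
#'   trimming.
#' @param phenotype label stored in the assignment.
#' @return a `group_assignment`: list with `phenotype`, `high_ids`,
#'   `low_ids`, `excluded_ids`, `n_per_group`, `sd_multiplier` and `values`.
#' @export
extreme_groups <- function(values, n = 10L, sd_multiplier = 2,
                           phenotype = "NDFD") {
  if (is.null(names(values))) {
    names(values) <- sprintf("S%03d", seq_along(values))
  }
  keep <- if (is.finite(sd_multiplier)) trim_outliers(values, sd_multiplier)
          else rep(TRUE, length(values))
  kept <- values[keep]
  if (length(kept) < 2L * n) {
    stop("need at least ", 2L * n, " samples after trimming, have ",
         length(kept), call. = FALSE)
  }
  ord <- order(-kept, names(kept))        # descending, ties by sample ID
  high <- names(kept)[ord[seq_len(n)]]
  low <- rev(names(kept)[ord[seq(length(kept) - n + 1L, length(kept))]])
  structure(list(phenotype = phenotype, high_ids = high, low_ids = low,
                 excluded_ids = names(values)[!keep],
                 n_per_group = as.integer(n), sd_multiplier = sd_multiplier,
                 values = values),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("group_assignment on %s: %d high, %d low, %d excluded\n",
              x$phenotype, length(x$high_ids), length(x$low_ids),
              length(x$excluded_ids)))
  invisible(x)
}

#' Two-sample t-test between high and low groups
#'
#' Student's pooled-variance t by default (`variant = "welch"` for unequal
#' variances). Degenerate inputs follow explicit conventions instead of
#' erroring: identical constant groups give `t = 0, p = 1`; two different
#' constants give a separation no t-test can quantify, reported as `t = Inf`
#' with the smallest representable p.
#'
#' @param high,low numeric vectors, each of length >= 2.
#' @param variant `"student"` (pooled) or `"welch"`.
#' @return list: `t`, `p`, `df`, `mean_high`, `mean_low`, and the per-group
#'   and pooled standard errors of the mean (`sem_high`, `sem_low`,
#'   `sem_pooled`).
#' @examples
#' group_ttest(c(5, 6, 7), c(1, 2, 3))
#' @export
group_ttest <- function(high, low, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(high) < 2L || length(low) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  sems <- list(sem_high = stats::sd(high) / sqrt(length(high)),
               sem_low = stats::sd(low) / sqrt(length(low)))
  sp2 <- ((length(high) - 1) * stats::var(high) +
            (length(low) - 1) * stats::var(low)) /
    (length(high) + length(low) - 2)
  sems$sem_pooled <- sqrt(sp2 / length(high) + sp2 / length(low)) / sqrt(2)
  if (stats::var(high) == 0 && stats::var(low) == 0) {
    if (mean(high) == mean(low)) {
      return(c(list(t = 0, p = 1, df = length(high) + length(low) - 2,
                    mean_high = mean(high), mean_low = mean(low)), sems))
    }
    return(c(list(t = sign(mean(high) - mean(low)) * Inf,
                  p = .Machine$double.xmin,
                  df = length(high) + length(low) - 2,
                  mean_high = mean(high), mean_low = mean(low)), sems))
  }
  tt <- stats::t.test(high, low, var.equal = variant == "student")
  c(list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), mean_high = mean(high),
         mean_low = mean(low)), sems)
}

#' Overlap between two extreme-group assignments
#'
#' Counts shared sample IDs between the high groups and between the low
#' groups of two assignments over the same cohort.
#'
#' @param a,b `group_assignment` objects.
#' @return named integer vector `c(high = , low = )`.
#' @export
group_overlap <- function(a, b) {
  c(high = length(intersect(a$high_ids, b$high_ids)),
    low = length(intersect(a$low_ids, b$low_ids)))
}

#' High-vs-low comparison of traits or genus abundances
#'
#' Runs [group_ttest()] for every column of `x` between the high and low
#' samples of an assignment. Trait tables conventionally use `alpha = 0.05`;
#' genus-level differential abundance uses the stricter `alpha = 0.01`
#' (set via `alpha`).
#'
#' @param x numeric matrix or data.frame, rows named by sample ID (a
#'   `composition_matrix` works directly; CLR values are the recommended
#'   scale for abundance comparisons).
#' @param assignment a `group_assignment`.
#' @param alpha significance threshold used for the `significant` flag.
#' @param variant passed to [group_ttest()].
#' @return data.frame: `feature`, `mean_high`, `mean_low`, `sem_high`,
#'   `sem_low`, `sem_pooled`, `t`, `p`, `significant`.
#' @export
group_comparison <- function(x, assignment, alpha = 0.01,
                             variant = c("student", "welch")) {
  variant <- match.arg(variant)
  m <- if (inherits(x, "composition_matrix")) unclass_matrix(x) else
    as.matrix(x)
  missing <- setdiff(c(assignment$high_ids, assignment$low_ids), rownames(m))
  if (length(missing)) {
    stop("assignment sample(s) absent from `x`: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  hi <- m[assignment$high_ids, , drop = FALSE]
  lo <- m[assignment$low_ids, , drop = FALSE]
  rows <- lapply(seq_len(ncol(m)), function(j) {
    r <- group_ttest(hi[, j], lo[, j], variant)
    data.frame(feature = colnames(m)[j], mean_high = r$mean_high,
               mean_low = r$mean_low, sem_high = r$sem_high,
               sem_low = r$sem_low, sem_pooled = r$sem_pooled,
               t = r$t, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < alpha
  out
}
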