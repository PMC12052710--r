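#' Specification of the two-part association model
#'
#' Collects the tunable parameters of the microbiome-wide association screen:
#' the prevalence boundary routing genera between the binary
#' (presence/absence) and quantitative (CLR abundance) model parts, the
#' number of principal-component covariates, the permutation budget, and the
#' family-wise significance threshold.
#'
#' With `adaptive = TRUE`, permutations for each genus are drawn in blocks
#' and stop early once `adaptive_min_hits` permuted statistics have reached
#' the observed one — at that point the p-value estimate is already precise
#' enough to rule out significance, so the full budget is spent only on the
#' genera that need it (the scheme used by large-scale permutation GWAS
#' tools). The estimate `(1 + hits) / (1 + drawn)` remains valid and never
#' returns zero.
#'
#' @param prevalence_threshold routing boundary (default 0.60): genera with
#'   prevalence below it are tested on presence/absence, the rest on CLR
#'   abundance.
#' @param n_pcs number of CLR principal components used as covariates
#'   (default 3).
#' @param n_permutations permutation budget per genus (default 10000).
#' @param alpha family-wise significance threshold after Bonferroni
#'   adjustment (default 0.01).
#' @param pseudocount CLR pseudocount (default 0.5).
#' @param adaptive logical; early-stopping permutation scheme (default
#'   `FALSE`).
#' @param adaptive_min_hits,adaptive_block early-stop tuning (defaults 10 and
#'   500).
#' @param seed base RNG seed; each genus uses a sub-seed derived from
#'   `(seed, genus index)` so results do not depend on processing order.
#' @return an `mwas_spec` list.
#' @export
mwas_spec <- function(prevalence_threshold = 0.6, n_pcs = 3L,
                      n_permutations = 10000L, alpha = 0.01,
                      pseudocount = 0.5, adaptive = FALSE,
                      adaptive_min_hits = 10L, adaptive_block = 500L,
                      seed = 1L) {
  if (prevalence_threshold <= 0 || prevalence_threshold > 1) {
    stop("`prevalence_threshold` must lie in (0, 1]", call. = FALSE)
  }
  if (n_pcs < 0L) stop("`n_pcs` must be >= 0", call. = FALSE)
  if (n_permutations < 99L) stop("`n_permutations` must be >= 99",
                                 call. = FALSE)
  structure(list(prevalence_threshold = prevalence_threshold,
                 n_pcs = as.integer(n_pcs),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, pseudocount = pseudocount,
                 adaptive = isTRUE(adaptive),
                 adaptive_min_hits = as.integer(adaptive_min_hits),
                 adaptive_block = as.integer(adaptive_block),
                 seed = as.integer(seed)),
            class = "mwas_spec")
}

#' Route genera between the binary and quantitative model parts
#'
#' Genera detected in fewer than `threshold` of the samples are tested on
#' presence/absence (binary part); genera at or above the threshold are
#' tested on their CLR abundance (quantitative part). The two sets partition
#' the genus universe.
#'
#' @param prev named per-genus prevalence vector in \[0, 1\] (see
#'   [prevalence()]).
#' @param threshold routing boundary, default 0.60.
#' @return list with character vectors `binary` and `quantitative`.
#' @examples
#' route_genera(c(g1 = 0.59, g2 = 0.60, g3 = 1.0))
#' @export
route_genera <- function(prev, threshold = 0.6) {
  if (any(prev < 0 | prev > 1)) stop("prevalence must lie in [0, 1]",
                                     call. = FALSE)
  nm <- names(prev)
  if (is.null(nm)) nm <- as.character(seq_along(prev))
  list(binary = nm[prev < threshold], quantitative = nm[prev >= threshold])
}

#' Permutation test of one genus term in a covariate-adjusted regression
#'
#' Fits `y ~ intercept + PCs + g` by least squares and takes the absolute
#' partial t-statistic of the genus term `g` (a 0/1 presence vector for the
#' binary part, a CLR column for the quantitative part). The p-value comes
#' from permuting `g` against the fixed `(y, PCs)`:
#' * exhaustive enumeration of all distinct arrangements of `g` when their
#'   number is at most `n_permutations` (all `choose(n, n1)` presence
#'   patterns for a binary `g`, all `n!` orders otherwise), giving
#'   `p = #\{|t*| >= |t|\} / #arrangements`;
#' * otherwise Monte-Carlo sampling with the add-one estimate
#'   `p = (1 + #\{|t*| >= |t|\}) / (1 + N)`, which is never zero.
#'
#' Ties between permuted and observed statistics count as exceedances. A
#' constant `g`, or a `g` collinear with the covariates, is unestimable and
#' returns `NA` statistics.
#'
#' @param y numeric phenotype vector.
#' @param g numeric predictor vector (same length).
#' @param pcs numeric covariate matrix (may be `NULL` for no adjustment).
#' @param n_permutations Monte-Carlo budget and exhaustiveness bound.
#' @param seed RNG seed for Monte-Carlo sampling.
#' @param method `"auto"` (exhaustive when feasible), `"exhaustive"` or
#'   `"montecarlo"`.
#' @param adaptive,adaptive_min_hits,adaptive_block early-stopping scheme for
#'   the Monte-Carlo path (see [mwas_spec()]).
#' @return list: `coefficient` (least-squares estimate of the genus term),
#'   `statistic` (observed |t|), `p`, `method` (`"exhaustive"` or
#'   `"montecarlo"`), `n_used` (arrangements or draws evaluated).
#' @examples
#' permutation_association(c(10, 9, 1, 2), c(1, 1, 0, 0), NULL,
#'                         method = "exhaustive")$p  # 1/3
#' @export
permutation_association <- function(y, g, pcs = NULL,
                                    n_permutations = 10000L, seed = 1L,
                                    method = c("auto", "exhaustive",
                                               "montecarlo"),
                                    adaptive = FALSE,
                                    adaptive_min_hits = 10L,
                                    adaptive_block = 500L) {
  method <- match.arg(method)
  n <- length(y)
  if (length(g) != n) stop("`y` and `g` must have equal length", call. = FALSE)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (nrow(pcs) != n) stop("`pcs` rows must match `y`", call. = FALSE)
  }
  Z <- cbind(rep(1, n), pcs)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) Z <- Z[, seq_len(qz$rank), drop = FALSE]
  Qz <- qr.Q(qr(Z))
  ry <- y - Qz %*% crossprod(Qz, y)
  ryy <- sum(ry^2)
  df <- n - ncol(Qz) - 1L
  if (df < 1L) stop("not enough samples for the design", call. = FALSE)

  stat_fun <- function(G) {
    # FWL: with y pre-residualized, t of g needs only g's residual moments
    qg <- crossprod(Qz, G)                     # k x N
    s_gg <- colSums(G^2) - colSums(qg^2)
    s_gy <- as.vector(crossprod(G, ry))
    tol <- 1e-10 * max(colSums(G^2), 1)
    est <- s_gg > tol
    beta <- ifelse(est, s_gy / s_gg, NA_real_)
    rss <- pmax(ryy - ifelse(est, s_gy^2 / s_gg, 0), 0)
    tt <- ifelse(est, abs(beta) / sqrt(pmax(rss, 0) / df / s_gg), NA_real_)
    tt[est & rss <= 1e-10 * max(ryy, 1)] <-
      ifelse(abs(beta[est & rss <= 1e-10 * max(ryy, 1)]) <= 1e-12, 0, Inf)
    list(t = tt, beta = beta)
  }

  obs <- stat_fun(matrix(g, ncol = 1L))
  if (is.na(obs$t)) {
    return(list(coefficient = NA_real_, statistic = NA_real_, p = NA_real_,
                method = NA_character_, n_used = 0L))
  }

  is_binary <- all(g %in% c(0, 1))
  n_arr <- if (is_binary) choose(n, sum(g)) else factorial(n)
  exhaustive <- method == "exhaustive" ||
    (method == "auto" && n_arr <= n_permutations)

  eps <- 1e-12 * max(obs$t, 1)
  if (exhaustive) {
    if (is_binary) {
      pos <- utils::combn(n, sum(g))
      G <- matrix(0, n, ncol(pos))
      G[cbind(as.vector(pos), rep(seq_len(ncol(pos)), each = nrow(pos)))] <- 1
    } else {
      if (n > 9L) stop("exhaustive enumeration limited to n <= 9 for ",
                       "non-binary predictors", call. = FALSE)
      perms <- all_permutations(n)
      G <- matrix(g[t(perms)], n, nrow(perms))
    }
    st <- stat_fun(G)$t
    st[is.na(st)] <- 0          # degenerate arrangements cannot exceed
    p <- mean(st >= obs$t - eps)
    return(list(coefficient = obs$beta, statistic = obs$t, p = p,
                method = "exhaustive", n_used = ncol(G)))
  }

  block <- if (adaptive) min(adaptive_block, n_permutations) else n_permutations
  mc <- with_seed(seed, {
    hits <- 0L
    drawn <- 0L
    while (drawn < n_permutations) {
      b <- min(block, n_permutations - drawn)
      # b random permutations at once: order iid uniform keys within columns
      keys <- stats::runif(n * b)
      ord <- order(rep.int(seq_len(b), rep.int(n, b)), keys)
      st <- stat_fun(matrix(g[((ord - 1L) %% n) + 1L], n, b))$t
      st[is.na(st)] <- 0
      hits <- hits + sum(st >= obs$t - eps)
      drawn <- drawn + b
      if (adaptive && hits >= adaptive_min_hits) break
    }
    list(hits = hits, drawn = drawn)
  })
  list(coefficient = obs$beta, statistic = obs$t,
       p = (1 + mc$hits) / (1 + mc$drawn), method = "montecarlo",
       n_used = mc$drawn)
}

#' Bonferroni selection over a family of association results
#'
#' Adjusts p-values as `min(1, m * p)` and flags results significant when the
#' adjusted p falls below `alpha`.
#'
#' @param results data.frame with a `p` column (rows with `NA` p are never
#'   significant).
#' @param m family size; must be at least the number of non-missing tests.
#' @param alpha significance threshold (default 0.01).
#' @return `results` with columns `p_adjusted` and `significant` appended.
#' @export
bonferroni_select <- function(results, m, alpha = 0.01) {
  if (m < 1L) stop("family size `m` must be >= 1", call. = FALSE)
  if (m < sum(!is.na(results$p))) {
    stop("family size `m` is smaller than the number of tests", call. = FALSE)
  }
  if (nrow(results) == 0L) {
    results$p_adjusted <- numeric(0)
    results$significant <- logical(0)
    return(results)
  }
  results$p_adjusted <- pmin(1, m * results$p)
  results$significant <- !is.na(results$p_adjusted) &
    results$p_adjusted < alpha
  results
}

#' Two-part microbiome-wide association screen
#'
#' Runs the full MWAS over a genus table: computes per-genus prevalence,
#' routes each genus to the binary (presence/absence) or quantitative (CLR
#' abundance) part, adjusts both parts for the leading CLR principal
#' components, obtains permutation p-values per genus, and applies a
#' Bonferroni correction across the combined family of all genera.
#'
#' @param abundance a `composition_matrix` of kind `"raw_counts"` or
#'   `"depth_normalized"`.
#' @param phenotype named numeric vector over the same samples.
#' @param spec an [mwas_spec()].
#' @param target label stored in the result.
#' @return data.frame with one row per genus: `feature`, `target`, `method`,
#'   `part`, `prevalence`, `statistic` (|t|), `coefficient`, `p`,
#'   `p_adjusted`, `significant`.
#' @export
mwas_screen <- function(abundance, phenotype, spec = mwas_spec(),
                        target = "NDFD") {
  if (composition_kind(abundance) == "raw_counts") {
    abundance <- normalize_to_min_depth(abundance)
  }
  m <- unclass_matrix(abundance)
  y <- match_samples(phenotype, rownames(m), "phenotype")
  prev <- prevalence(abundance)
  routing <- route_genera(prev, spec$prevalence_threshold)
  clr_obj <- clr_transform(abundance, spec$pseudocount)
  clrm <- unclass_matrix(clr_obj)
  pcs <- if (spec$n_pcs > 0L) principal_components(clr_obj, spec$n_pcs)
         else NULL

  genera <- colnames(m)
  part <- ifelse(genera %in% routing$binary, "binary", "quantitative")
  X <- clrm
  X[, part == "binary"] <- (m[, part == "binary", drop = FALSE] > 0) + 0

  n <- nrow(X)
  constant <- apply(X, 2L, function(v) length(unique(v)) < 2L)
  # exhaustive enumeration where the arrangement count is within budget
  # (only reachable for small cohorts)
  n_arr <- rep(Inf, length(genera))
  bi <- part == "binary" & !constant
  n_arr[bi] <- choose(n, colSums(X[, bi, drop = FALSE]))
  if (n <= 9L) n_arr[part == "quantitative" & !constant] <- factorial(n)
  exh <- which(!constant & n_arr <= spec$n_permutations)

  stat <- coefficient <- p <- rep(NA_real_, length(genera))
  for (j in exh) {
    r <- permutation_association(y, X[, j], pcs,
                                 n_permutations = spec$n_permutations,
                                 seed = derive_seed(spec$seed, j),
                                 method = "exhaustive")
    stat[j] <- r$statistic
    coefficient[j] <- r$coefficient
    p[j] <- r$p
  }

  mc <- setdiff(which(!constant), exh)
  if (length(mc)) {
    r <- mwas_batch_permute(X[, mc, drop = FALSE], y, pcs, spec)
    stat[mc] <- r$statistic
    coefficient[mc] <- r$coefficient
    p[mc] <- r$p
  }

  df <- data.frame(feature = genera, target = target,
                   method = paste0("mwas_", part), part = part,
                   prevalence = unname(prev), statistic = stat,
                   coefficient = coefficient, p = p,
                   stringsAsFactors = FALSE)
  # conservative family size: every genus in the table, tested or not
  bonferroni_select(df, m = length(genera), alpha = spec$alpha)
}

# Monte-Carlo permutation p-values for many genus predictors at once.
#
# All genera share one permutation stream (drawn from spec$seed, so results
# are independent of genus order). Shuffling a predictor g against fixed
# (y, PCs) gives the same statistic as applying the inverse shuffle to
# (y, PCs) with g fixed; since the permutation set is uniform either way,
# the shared permuted covariate block can be reused for every genus, turning
# the screen into a handful of matrix products per block.
#
# With spec$adaptive, genera whose exceedance count has reached
# adaptive_min_hits stop consuming further blocks (their p-value is already
# resolvably non-significant); the add-one estimate stays valid per genus.
mwas_batch_permute <- function(X, y, pcs, spec) {
  n <- nrow(X)
  G <- ncol(X)
  Z <- cbind(rep(1, n), pcs)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) Z <- Z[, seq_len(qz$rank), drop = FALSE]
  Qz <- qr.Q(qr(Z))
  k <- ncol(Qz)
  ry <- as.vector(y - Qz %*% crossprod(Qz, y))
  ryy <- sum(ry^2)
  df <- n - k - 1L
  if (df < 1L) stop("not enough samples for the design", call. = FALSE)
  sum_g2 <- colSums(X^2)

  t_from_moments <- function(s_gy, qg2, sg2) {
    # qg2: sum of squared projections of g onto the covariate space;
    # sg2: per-genus sum of squares (recycled along rows for matrix input)
    s_gg <- if (is.matrix(qg2)) sweep(-qg2, 1L, sg2, `+`) else sg2 - qg2
    s_gg <- pmax(s_gg, 0)
    est <- s_gg > 1e-10 * max(sum_g2, 1)
    beta <- ifelse(est, s_gy / s_gg, NA_real_)
    rss <- pmax(ryy - ifelse(est, s_gy^2 / s_gg, 0), 0)
    tt <- ifelse(est, abs(beta) / sqrt(rss / df / s_gg), NA_real_)
    degen <- est & rss <= 1e-10 * max(ryy, 1)
    tt[degen] <- ifelse(abs(beta[degen]) <= 1e-12, 0, Inf)
    list(t = tt, beta = beta)
  }

  qg0 <- crossprod(Qz, X)                       # k x G
  obs <- t_from_moments(as.vector(crossprod(X, ry)), colSums(qg0^2), sum_g2)
  t_obs <- obs$t
  # exceedance threshold; an infinite observed t is matched only by Inf
  thresh <- t_obs - 1e-12 * pmax(t_obs, 1)
  thresh[!is.finite(t_obs) & !is.na(t_obs)] <- Inf

  hits <- integer(G)
  drawn <- integer(G)
  active <- which(!is.na(t_obs))
  F_fix <- cbind(ry, Qz)                        # n x (k + 1)
  block <- if (spec$adaptive) min(spec$adaptive_block, spec$n_permutations)
           else min(spec$n_permutations, 2000L)

  with_seed(spec$seed, {
    done <- 0L
    while (done < spec$n_permutations && length(active)) {
      b <- min(block, spec$n_permutations - done)
      keys <- stats::runif(n * b)
      ord <- order(rep.int(seq_len(b), rep.int(n, b)), keys,
                   method = "radix")
      idx <- ((ord - 1L) %% n) + 1L             # n x b permutations, shared
      Xa <- X[, active, drop = FALSE]
      s_gy <- crossprod(Xa, matrix(ry[idx], n, b))        # |active| x b
      qg2 <- 0
      for (l in seq_len(k)) {
        qg2 <- qg2 + crossprod(Xa, matrix(Qz[idx, l], n, b))^2
      }
      st <- t_from_moments(s_gy, qg2, sum_g2[active])$t
      st[is.na(st)] <- 0
      exceed <- st >= thresh[active]
      hits[active] <- hits[active] + rowSums(exceed)
      drawn[active] <- drawn[active] + b
      done <- done + b
      if (spec$adaptive) {
        active <- active[hits[active] < spec$adaptive_min_hits]
      }
    }
  })
  p <- ifelse(drawn > 0L, (1 + hits) / (1 + drawn), NA_real_)
  p[is.na(t_obs)] <- NA_real_
  list(statistic = t_obs, coefficient = obs$beta, p = p)
}
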