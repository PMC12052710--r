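#' Configuration for the synthetic cohort generator
#'
#' Defines a simulated fattening-lamb cohort: a genus-level abundance table
#' with heterogeneous prevalence, a fiber degradation-rate phenotype driven by
#' a small set of causal genera, a negatively linked feed conversion ratio,
#' and internal-marker concentration panels from which the degradation rates
#' can be re-derived exactly.
#'
#' Defaults mirror the scale of the motivating study: 190 animals, 292
#' genera, per-genus prevalence spanning 0.2--1.0 so that genera fall on both
#' sides of the 60% routing boundary of the two-part association model.
#'
#' Causal effects can be given explicitly through `effect_sizes`, or derived
#' from variance targets: each quantitative causal genus contributes a
#' fraction `quant_r2` of the phenotype variance (regression weight in
#' phenotype units per CLR unit), and the binary causal genus shifts the
#' phenotype by `binary_shift * noise_sd` when present.
#'
#' @param n_samples number of animals (default 190).
#' @param n_genera number of genera (default 292).
#' @param n_causal_quant number of causal genera acting through CLR abundance
#'   (planted at structural prevalence 1, i.e. the quantitative model part).
#' @param n_causal_binary number of causal genera acting through presence /
#'   absence (planted below the 60% prevalence boundary).
#' @param quant_r2 target fraction of phenotype variance per quantitative
#'   causal genus (default 0.15).
#' @param binary_shift presence effect of each binary causal genus, in units
#'   of `noise_sd` (default 2).
#' @param binary_prevalence structural presence probability of binary causal
#'   genera (default 0.4).
#' @param effect_sizes optional explicit `list(quant = , binary = )` of
#'   regression weights; overrides `quant_r2` / `binary_shift`.
#' @param ndfd_mean,noise_sd mean and residual SD of the NDF degradation rate
#'   (percent; defaults 55 and 4).
#' @param adfd_mean mean ADF degradation rate (percent, default 45; ADF is
#'   less degradable than NDF).
#' @param adfd_noise_sd residual SD of ADFD around its NDFD-tracking center
#'   (default 2; ADFD follows 0.8 x the NDFD deviation, so the two rates are
#'   strongly concordant and their extreme groups overlap heavily).
#' @param fcr_intercept,fcr_slope,fcr_noise_sd linear link from NDFD to the
#'   feed conversion ratio; the default slope -0.05 with residual SD 0.7
#'   yields a moderate negative correlation (about -0.5) and FCR values near
#'   6, the realistic range for fattening lambs.
#' @param depth_range integer min/max sequencing depth per sample.
#' @param prevalence_range per-genus structural presence probability bounds,
#'   in (0, 1].
#' @param genus_dispersion log-normal SD of per-sample, per-genus abundance
#'   fluctuations (default 0.8), the biological overdispersion on top of
#'   multinomial counting noise.
#' @param pseudocount pseudocount used for the generator's internal CLR
#'   (must match the analysis convention; default 0.5).
#' @param seed integer RNG seed; identical configs give identical cohorts.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 190L, n_genera = 292L,
                       n_causal_quant = 4L, n_causal_binary = 1L,
                       quant_r2 = 0.15, binary_shift = 2,
                       binary_prevalence = 0.4, effect_sizes = NULL,
                       ndfd_mean = 55, noise_sd = 4,
                       adfd_mean = 45, adfd_noise_sd = 2,
                       fcr_intercept = 8.85, fcr_slope = -0.05,
                       fcr_noise_sd = 0.7,
                       depth_range = c(20000L, 60000L),
                       prevalence_range = c(0.2, 1),
                       genus_dispersion = 0.8, pseudocount = 0.5,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_genera = as.integer(n_genera),
              n_causal_quant = as.integer(n_causal_quant),
              n_causal_binary = as.integer(n_causal_binary),
              quant_r2 = quant_r2, binary_shift = binary_shift,
              binary_prevalence = binary_prevalence,
              effect_sizes = effect_sizes,
              ndfd_mean = ndfd_mean, noise_sd = noise_sd,
              adfd_mean = adfd_mean, adfd_noise_sd = adfd_noise_sd,
              fcr_intercept = fcr_intercept, fcr_slope = fcr_slope,
              fcr_noise_sd = fcr_noise_sd,
              depth_range = as.integer(depth_range),
              prevalence_range = as.numeric(prevalence_range),
              genus_dispersion = genus_dispersion,
              pseudocount = pseudocount,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 1L || cfg$n_genera < 1L) {
    stop("`n_samples` and `n_genera` must be positive", call. = FALSE)
  }
  if (cfg$n_causal_quant < 0L || cfg$n_causal_binary < 0L ||
      cfg$n_causal_quant + cfg$n_causal_binary > cfg$n_genera) {
    stop("causal genus counts must be non-negative and sum to at most ",
         "`n_genera`", call. = FALSE)
  }
  if (length(cfg$depth_range) != 2L || cfg$depth_range[1] < 1L ||
      cfg$depth_range[2] < cfg$depth_range[1]) {
    stop("`depth_range` must be an increasing pair with min >= 1",
         call. = FALSE)
  }
  pr <- cfg$prevalence_range
  if (length(pr) != 2L || pr[1] <= 0 || pr[2] > 1 || pr[2] < pr[1]) {
    stop("`prevalence_range` bounds must lie in (0, 1] and be ordered",
         call. = FALSE)
  }
  if (is.null(cfg$effect_sizes) &&
      cfg$n_causal_quant * cfg$quant_r2 >= 1) {
    stop("total quantitative variance share `n_causal_quant * quant_r2` ",
         "must be < 1", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  if (cfg$binary_prevalence <= 0 || cfg$binary_prevalence >= 0.6) {
    stop("`binary_prevalence` must lie in (0, 0.6) so binary causal genera ",
         "stay below the routing boundary", call. = FALSE)
  }
  invisible(cfg)
}

# Draw order inside one abundance realization (documented contract):
# (1) per-sample depths; (2) per-genus log-normal base abundances;
# (3) per-genus structural prevalence; (4) causal genus positions;
# (5) presence indicators (sample-major); (6) per-cell dispersion jitter;
# (7) per-sample multinomial counts.
generate_abundance_once <- function(cfg, seed) {
  n <- cfg$n_samples
  G <- cfg$n_genera
  with_seed(seed, {
    depths <- if (cfg$depth_range[1] == cfg$depth_range[2]) {
      rep(cfg$depth_range[1], n)
    } else {
      sample(seq(cfg$depth_range[1], cfg$depth_range[2]), n, replace = TRUE)
    }
    base <- stats::rlnorm(G, meanlog = 0, sdlog = 1.5)
    prev <- stats::runif(G, cfg$prevalence_range[1], cfg$prevalence_range[2])
    n_causal <- cfg$n_causal_quant + cfg$n_causal_binary
    causal <- if (n_causal > 0L) sample.int(G, n_causal) else integer(0)
    causal_quant <- utils::head(causal, cfg$n_causal_quant)
    causal_binary <- utils::tail(causal, cfg$n_causal_binary)
    if (length(causal_quant)) {
      # quantitative-part genera: never structurally absent, and abundant
      # enough that sampling zeros are negligible at realistic depths
      prev[causal_quant] <- 1
      base[causal_quant] <- pmax(base[causal_quant],
                                 stats::quantile(base, 0.7))
    }
    if (length(causal_binary)) {
      prev[causal_binary] <- cfg$binary_prevalence
      base[causal_binary] <- pmax(base[causal_binary],
                                  stats::quantile(base, 0.6))
    }
    presence <- matrix(stats::runif(n * G) < rep(prev, each = n), n, G)
    jitter <- matrix(stats::rlnorm(n * G, 0, cfg$genus_dispersion), n, G)
    intensity <- presence * jitter * rep(base, each = n)
    empty <- rowSums(intensity) == 0
    if (any(empty)) {   # pathological tiny configs: force the top genus in
      j <- which.max(base)
      intensity[empty, j] <- base[j]
    }
    counts <- t(vapply(seq_len(n), function(i) {
      as.integer(stats::rmultinom(1L, depths[i], intensity[i, ]))
    }, integer(G)))
    dimnames(counts) <- list(sprintf("S%03d", seq_len(n)),
                             sprintf("Genus_%04d", seq_len(G)))
    out <- composition_matrix(counts, "raw_counts")
    attr(out, "planted_prevalence") <- prev
    attr(out, "causal_quant") <- causal_quant
    attr(out, "causal_binary") <- causal_binary
    out
  })
}

#' Generate a synthetic genus-level count table
#'
#' Per-genus log-normal base abundances with Bernoulli zero-inflation
#' (structural absence applied before counting, so genera below the 60%
#' prevalence boundary are genuinely absent, not merely under-sampled),
#' per-cell log-normal overdispersion, and a per-sample multinomial draw at a
#' depth sampled from `depth_range`.
#'
#' When the configuration plants causal genera, the realized table is checked
#' against the routing boundary (quantitative causal genera must show
#' empirical prevalence >= 60%, binary causal genera < 60%) and regenerated
#' from a derived seed on violation.
#'
#' @param config a [sim_config()].
#' @return a `composition_matrix` of kind `"raw_counts"` with attributes
#'   `planted_prevalence`, `causal_quant` and `causal_binary` (column
#'   indices of the planted causal genera).
#' @examples
#' x <- generate_abundance(sim_config(n_samples = 5, n_genera = 8, seed = 1,
#'                                    n_causal_quant = 0, n_causal_binary = 0))
#' dim(x)
#' @export
generate_abundance <- function(config) {
  validate_sim_config(config)
  for (attempt in 0:24) {
    seed <- if (attempt == 0L) config$seed else {
      derive_seed(config$seed, 7000L + attempt)
    }
    out <- generate_abundance_once(config, seed)
    if (routing_classes_ok(out, config)) return(out)
  }
  stop("could not realize causal genera in their prevalence classes; ",
       "adjust `binary_prevalence` or sequencing depth", call. = FALSE)
}

routing_classes_ok <- function(ab, cfg) {
  cq <- attr(ab, "causal_quant")
  cb <- attr(ab, "causal_binary")
  if (!length(cq) && !length(cb)) return(TRUE)
  prev <- prevalence(ab)
  all(prev[cq] >= 0.6) && all(prev[cb] < 0.6)
}

#' Construct a marker panel that encodes a known degradation rate
#'
#' Inverse of [degradation_rate()]: given a true degradation rate and the
#' feed-side concentrations, solves for the fiber concentration in rumen
#' contents, `FB = FA * (1 - rate) * (B/A)`, so that the acid-insoluble-ash
#' formula recovers the rate exactly. Used by the cohort generator and by
#' round-trip tests.
#'
#' @param true_rate degradation rate as a fraction in \[0, 1\] (vectorized).
#' @param feed_marker_conc acid-insoluble ash in feed (`A`), > 0.
#' @param digesta_marker_conc acid-insoluble ash in rumen contents (`B`);
#'   must exceed `feed_marker_conc` — the indigestible marker concentrates in
#'   digesta.
#' @param feed_fiber_conc NDF or ADF concentration in feed (`FA`), > 0.
#' @param fiber_kind `"NDF"` or `"ADF"`.
#' @return a [marker_measurement()].
#' @examples
#' m <- generate_marker_panel(0.625, 2, 4, 400)
#' degradation_rate(m)  # 62.5
#' @export
generate_marker_panel <- function(true_rate, feed_marker_conc,
                                  digesta_marker_conc, feed_fiber_conc,
                                  fiber_kind = c("NDF", "ADF")) {
  fiber_kind <- match.arg(fiber_kind)
  if (any(true_rate < 0) || any(true_rate > 1)) {
    stop("`true_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (any(feed_marker_conc <= 0) || any(feed_fiber_conc <= 0)) {
    stop("feed concentrations must be positive", call. = FALSE)
  }
  if (any(digesta_marker_conc <= feed_marker_conc)) {
    stop("the indigestible marker must concentrate in digesta: ",
         "`digesta_marker_conc` must exceed `feed_marker_conc`",
         call. = FALSE)
  }
  fb <- feed_fiber_conc * (1 - true_rate) *
    (digesta_marker_conc / feed_marker_conc)
  marker_measurement(A = feed_marker_conc, B = digesta_marker_conc,
                     FA = feed_fiber_conc, FB = fb, fiber_kind = fiber_kind)
}

#' Generate a full synthetic cohort
#'
#' Builds the abundance table via [generate_abundance()], then the degradation
#' phenotypes and feed-efficiency traits on top of it:
#' \deqn{NDFD_i = \mu + \sum_j \beta_j (clr_{ij} - \bar{clr_j})
#'   + \sum_j \gamma_j (1[x_{ij} > 0] - \bar{1_j}) + \epsilon_i}
#' \deqn{FCR_i = a + b \cdot NDFD_i + \eta_i}
#' ADFD tracks the realized NDFD (scaled 0.8 around its own mean) with its
#' own residual, giving the strong concordance expected between the two
#' fiber fractions.
#' Internal-marker panels for both fiber kinds are constructed per animal via
#' [generate_marker_panel()], so [degradation_rate()] applied to the
#' phenotype table's marker columns reproduces the planted rates exactly.
#' Body weights grow linearly at `ADG = ADFI / FCR` from an individual
#' 80-day weight, so [growth_metrics()] recovers the planted FCR.
#'
#' @param config a [sim_config()].
#' @return a list with elements `abundance` (`composition_matrix`,
#'   raw counts), `phenotype` (data.frame: sample IDs, BW series, ADFI, FCR,
#'   marker concentrations, NDFD, ADFD), `taxonomy` (data.frame genus /
#'   phylum, synthetic labels), and `truth` (a `truth_record`: causal genera
#'   with classes and effects, per-sample true rates, FCR link).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  ab <- generate_abundance(config)
  n <- config$n_samples
  clrm <- unclass_matrix(clr_transform(normalize_to_min_depth(ab),
                                       config$pseudocount))
  cq <- attr(ab, "causal_quant")
  cb <- attr(ab, "causal_binary")

  pres <- unclass_matrix(ab)[, cb, drop = FALSE] > 0
  cc <- if (length(cq)) scale(clrm[, cq, drop = FALSE], center = TRUE,
                              scale = FALSE) else NULL
  pc <- if (length(cb)) scale(pres + 0, center = TRUE, scale = FALSE)
        else NULL
  if (!is.null(config$effect_sizes)) {
    beta <- rep_len(as.numeric(config$effect_sizes$quant %||% 0), length(cq))
    gamma <- rep_len(as.numeric(config$effect_sizes$binary %||% 0), length(cb))
  } else {
    gamma <- rep(config$binary_shift * config$noise_sd, length(cb))
    beta <- calibrate_quant_effects(cc, if (length(cb)) drop(pc %*% gamma)
                                        else rep(0, n),
                                    config$noise_sd, config$quant_r2)
  }

  lin <- rep(0, n)
  if (length(cq)) lin <- lin + drop(cc %*% beta)
  if (length(cb)) lin <- lin + drop(pc %*% gamma)

  ph <- with_seed(derive_seed(config$seed, 2L), {
    eps <- truncated_residuals(config$ndfd_mean + lin, config$noise_sd)
    ndfd <- config$ndfd_mean + lin + eps
    # ADFD tracks NDFD (same fermentation event), scaled and jittered; the
    # high NDFD-ADFD concordance drives the extreme-group overlaps
    center_a <- config$adfd_mean + 0.8 * (ndfd - config$ndfd_mean)
    eps_a <- truncated_residuals(center_a, config$adfd_noise_sd)
    adfd <- center_a + eps_a
    fcr <- config$fcr_intercept + config$fcr_slope * ndfd +
      stats::rnorm(n, 0, config$fcr_noise_sd)
    fcr <- pmax(fcr, 1.5)   # floor far below any realistic FCR
    b_ratio <- stats::runif(n, 1.6, 2.4)
    adfi <- pmax(stats::rnorm(n, 1.55, 0.15), 0.5)
    bw80 <- pmax(stats::rnorm(n, 20, 2), 12)
    list(ndfd = ndfd, adfd = adfd, fcr = fcr, b_ratio = b_ratio,
         adfi = adfi, bw80 = bw80)
  })

  A <- 2
  B <- A * ph$b_ratio
  m_ndf <- generate_marker_panel(ph$ndfd / 100, A, B, 400, "NDF")
  m_adf <- generate_marker_panel(ph$adfd / 100, A, B, 220, "ADF")
  adg <- ph$adfi / ph$fcr
  ages <- seq(80L, 180L, by = 20L)
  bw <- outer(adg, ages - 80L) + ph$bw80
  colnames(bw) <- paste0("BW_", ages)

  phen <- data.frame(sample_id = rownames(ab), bw, ADFI = ph$adfi,
                     FCR = ph$fcr, AIA_feed = m_ndf$A,
                     AIA_digesta = m_ndf$B, NDF_feed = m_ndf$FA,
                     NDF_digesta = m_ndf$FB, ADF_feed = m_adf$FA,
                     ADF_digesta = m_adf$FB, NDFD = ph$ndfd,
                     ADFD = ph$adfd, stringsAsFactors = FALSE)
  rownames(phen) <- NULL

  tax <- synthetic_taxonomy(colnames(ab), derive_seed(config$seed, 3L))

  genus_names <- colnames(ab)
  causal <- data.frame(
    genus = c(genus_names[cq], genus_names[cb]),
    class = c(rep("quantitative", length(cq)), rep("binary", length(cb))),
    effect = c(beta, gamma),
    planted_prevalence = attr(ab, "planted_prevalence")[c(cq, cb)],
    stringsAsFactors = FALSE)
  truth <- structure(list(causal = causal,
                          true_rate_per_sample = ph$ndfd / 100,
                          true_adf_rate_per_sample = ph$adfd / 100,
                          fcr_link = c(intercept = config$fcr_intercept,
                                       slope = config$fcr_slope),
                          config = config),
                     class = "truth_record")
  list(abundance = ab, phenotype = phen, taxonomy = tax, truth = truth)
}

# Solve for quantitative effect sizes so that each causal genus's marginal
# phenotype R-squared (expectation over the residual draw) equals `r2`.
# Because causal CLR columns are mutually correlated, the system
#   cov(c_j, C beta + u)^2 / (v_j (var(C beta + u) + sigma^2)) = r2
# has no closed form; a fixed-point iteration rescaling each beta_j by
# sqrt(r2 / R2_j) converges quickly for the modest correlations seen in
# compositional data. Signs alternate (+, -, ...) across causal genera.
calibrate_quant_effects <- function(cc, u, sigma, r2, max_iter = 200L) {
  if (is.null(cc) || ncol(cc) == 0L) return(numeric(0))
  q <- ncol(cc)
  v <- apply(cc, 2L, stats::var)
  sgn <- rep_len(c(1, -1), q)
  beta <- sgn * sqrt(r2 * sigma^2 / ((1 - q * r2) * pmax(v, 1e-12)))
  for (it in seq_len(max_iter)) {
    L <- drop(cc %*% beta) + u
    Vtot <- stats::var(L) + sigma^2
    covs <- drop(stats::cov(cc, L))
    r2_now <- covs^2 / (v * Vtot)
    if (all(abs(r2_now - r2) < 1e-9 * r2)) break
    scale_j <- sqrt(r2 / pmax(r2_now, 1e-12))
    beta <- beta * pmin(scale_j, 4)    # damped to avoid sign-flip overshoot
  }
  beta
}

# Residuals drawn so that mean + lin + eps stays inside (0.5, 99.5) percent:
# out-of-range draws are redrawn (the trait is a percentage by construction).
truncated_residuals <- function(center, sd, lower = 0.5, upper = 99.5) {
  eps <- stats::rnorm(length(center), 0, sd)
  bad <- which(center + eps <= lower | center + eps >= upper)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    eps[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[center[bad] + eps[bad] <= lower |
                 center[bad] + eps[bad] >= upper]
    tries <- tries + 1L
  }
  if (length(bad)) {
    stop("phenotype mean/SD place the trait outside the (0, 100)% range",
         call. = FALSE)
  }
  eps
}

synthetic_taxonomy <- function(genera, seed) {
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria", "Spirochaetes", "Verrucomicrobia")
  probs <- c(0.50, 0.28, 0.10, 0.06, 0.03, 0.03)
  with_seed(seed, {
    data.frame(genus = genera,
               phylum = sample(phyla, length(genera), replace = TRUE,
                               prob = probs),
               stringsAsFactors = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
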