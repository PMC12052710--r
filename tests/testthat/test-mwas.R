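test_that("prevalence routing partitions genera at the 60% boundary", {
  r <- route_genera(c(g1 = 0.59, g2 = 0.60, g3 = 1.0, g4 = 0))
  expect_equal(r$binary, c("g1", "g4"))
  expect_equal(r$quantitative, c("g2", "g3"))

  set.seed(3)
  prev <- stats::setNames(runif(50), paste0("x", 1:50))
  r2 <- route_genera(prev, 0.6)
  expect_length(intersect(r2$binary, r2$quantitative), 0)
  expect_setequal(c(r2$binary, r2$quantitative), names(prev))
  expect_error(route_genera(c(a = 1.2)), "\\[0, 1\\]")
})

test_that("the hand-enumerated 4-sample case gives p = 1/3", {
  r <- permutation_association(c(10, 9, 1, 2), c(1, 1, 0, 0), NULL,
                               method = "exhaustive")
  expect_equal(r$p, 1 / 3)
  expect_equal(r$method, "exhaustive")
  expect_equal(r$n_used, 6L)
})

test_that("degenerate designs follow the documented conventions", {
  # constant phenotype: every permuted statistic ties at zero
  r <- permutation_association(rep(5, 8), c(1, 1, 1, 0, 0, 0, 1, 0), NULL,
                               n_permutations = 200, seed = 1)
  expect_equal(r$p, 1)
  # constant predictor: unestimable
  r2 <- permutation_association(rnorm(8), rep(1, 8), NULL,
                                n_permutations = 200, seed = 1)
  expect_true(is.na(r2$p))
})

test_that("Monte-Carlo p agrees with exhaustive enumeration for tiny n", {
  set.seed(41)
  for (i in 1:8) {
    n <- sample(5:7, 1)
    y <- rnorm(n)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) g[1:2] <- c(0, 1)
    ex <- permutation_association(y, g, NULL, method = "exhaustive")
    mc <- permutation_association(y, g, NULL, n_permutations = 10000,
                                  seed = 50 + i, method = "montecarlo")
    se <- sqrt(ex$p * (1 - ex$p) / 10000)
    expect_lt(abs(mc$p - ex$p), 3 * se + 1e-4)
  }
})

test_that("permutation p-values are reproducible and never zero", {
  set.seed(2)
  y <- rnorm(30)
  g <- rnorm(30)
  y <- y + 3 * g                      # overwhelming signal
  a <- permutation_association(y, g, NULL, n_permutations = 500, seed = 9)
  b <- permutation_association(y, g, NULL, n_permutations = 500, seed = 9)
  expect_identical(a$p, b$p)
  expect_gte(a$p, 1 / 501)
})

test_that("the observed statistic matches the lm partial t", {
  set.seed(13)
  y <- rnorm(40)
  g <- rnorm(40)
  pcs <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, paste0("PC", 1:3)))
  r <- permutation_association(y, g, pcs, n_permutations = 99, seed = 1)
  expect_equal(r$statistic, oracle_partial_t(y, g, pcs), tolerance = 1e-8)
})

test_that("Bonferroni selection adjusts and thresholds correctly", {
  res <- data.frame(feature = c("a", "b"), p = c(1e-4, 0.02))
  out <- bonferroni_select(res, m = 2, alpha = 0.01)
  expect_equal(out$p_adjusted, c(2e-4, 0.04))
  expect_equal(out$significant, c(TRUE, FALSE))

  single <- bonferroni_select(data.frame(p = 0.005), m = 1, alpha = 0.01)
  expect_true(single$significant)

  empty <- bonferroni_select(data.frame(p = numeric(0)), m = 1)
  expect_equal(nrow(empty), 0)
  expect_error(bonferroni_select(res, m = 0), ">= 1")
  expect_error(bonferroni_select(res, m = 1), "smaller")

  # monotone in alpha: tightening alpha can only shrink the selection
  set.seed(8)
  ps <- data.frame(p = runif(50, 0, 0.01))
  strict <- bonferroni_select(ps, 50, alpha = 0.005)$significant
  loose <- bonferroni_select(ps, 50, alpha = 0.01)$significant
  expect_true(all(loose[strict]))
})

test_that("the screen partitions genera and matches the reference test", {
  co <- generate_cohort(sim_config(n_samples = 40, n_genera = 12,
                                   n_causal_quant = 1, n_causal_binary = 0,
                                   depth_range = c(3000L, 5000L), seed = 15))
  y <- stats::setNames(co$phenotype$NDFD, co$phenotype$sample_id)
  spec <- mwas_spec(n_permutations = 4000, n_pcs = 2, seed = 77)
  scr <- mwas_screen(co$abundance, y, spec)
  expect_setequal(scr$part, c("binary", "quantitative"))
  expect_equal(nrow(scr), 12)

  norm <- normalize_to_min_depth(co$abundance)
  clrm <- clr_transform(norm)
  pcs <- principal_components(clrm, 2)
  prev <- prevalence(norm)
  for (j in c(1, 5, 9)) {
    g <- if (prev[j] < 0.6) as.numeric(unclass(co$abundance)[, j] > 0)
         else unclass(clrm)[, j]
    if (length(unique(g)) < 2) next
    ref <- permutation_association(y, g, pcs, n_permutations = 4000,
                                   seed = 123, method = "auto")
    expect_equal(scr$statistic[j], ref$statistic, tolerance = 1e-8)
    if (ref$method == "exhaustive") {
      expect_equal(scr$p[j], ref$p)
    } else {
      se <- sqrt(max(ref$p * (1 - ref$p), 2.5e-4) / 4000)
      expect_lt(abs(scr$p[j] - ref$p), 4 * se + 5e-3)
    }
  }
})

test_that("a strongly planted genus reaches Bonferroni significance", {
  co <- generate_cohort(sim_config(n_samples = 100, n_genera = 30,
                                   n_causal_quant = 1, n_causal_binary = 0,
                                   quant_r2 = 0.35,
                                   depth_range = c(5000L, 8000L), seed = 19))
  y <- stats::setNames(co$phenotype$NDFD, co$phenotype$sample_id)
  scr <- mwas_screen(co$abundance, y,
                     mwas_spec(n_permutations = 20000, adaptive = TRUE,
                               seed = 5))
  causal <- co$truth$causal$genus[1]
  expect_true(scr$significant[scr$feature == causal])
  # adaptive early stopping must not manufacture significance elsewhere
  expect_lte(sum(scr$significant), 3)
})
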