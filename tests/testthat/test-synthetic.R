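test_that("generation is deterministic under a fixed config", {
  cfg <- sim_config(n_samples = 12, n_genera = 8, n_causal_quant = 1,
                    n_causal_binary = 1, depth_range = c(2000L, 4000L),
                    seed = 5)
  a1 <- generate_abundance(cfg)
  a2 <- generate_abundance(cfg)
  expect_identical(unclass(a1)[, ], unclass(a2)[, ])

  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$phenotype, c2$phenotype)
  expect_identical(unclass(c1$abundance)[, ], unclass(c2$abundance)[, ])
  expect_identical(c1$truth$causal, c2$truth$causal)
})

test_that("full structural prevalence leaves no zero cells", {
  cfg <- sim_config(n_samples = 5, n_genera = 3, n_causal_quant = 0,
                    n_causal_binary = 0, prevalence_range = c(1, 1),
                    depth_range = c(5000L, 5000L), seed = 1)
  x <- generate_abundance(cfg)
  expect_true(all(unclass(x)[, ] > 0))
})

test_that("empirical prevalence spans both sides of the routing boundary", {
  x <- generate_abundance(sim_config(n_samples = 200, n_genera = 292,
                                     seed = 7))
  prev <- prevalence(x)
  expect_gt(sum(prev < 0.6), 30)
  expect_gt(sum(prev >= 0.6), 30)
})

test_that("marker panels encode the requested rate", {
  expect_equal(generate_marker_panel(0.625, 2, 4, 400)$FB, 300)
  expect_equal(generate_marker_panel(0, 2, 4, 400)$FB, 800)
  expect_equal(generate_marker_panel(1, 2, 4, 400)$FB, 0)
  expect_error(generate_marker_panel(0.5, 4, 2, 400), "concentrate")
  expect_error(generate_marker_panel(1.2, 2, 4, 400), "0, 1")
})

test_that("cohort truth record respects the routing classes", {
  co <- generate_cohort(sim_config(n_samples = 100, n_genera = 60,
                                   n_causal_quant = 3, n_causal_binary = 1,
                                   depth_range = c(8000L, 12000L), seed = 9))
  prev <- prevalence(co$abundance)
  ca <- co$truth$causal
  expect_true(all(ca$genus %in% colnames(co$abundance)))
  expect_true(all(prev[ca$genus[ca$class == "quantitative"]] >= 0.6))
  expect_true(all(prev[ca$genus[ca$class == "binary"]] < 0.6))
})

test_that("phenotype marker columns reproduce the planted rates exactly", {
  co <- small_cohort(seed = 3)
  ph <- co$phenotype
  ndfd <- degradation_rate(marker_measurement(ph$AIA_feed, ph$AIA_digesta,
                                              ph$NDF_feed, ph$NDF_digesta))
  adfd <- degradation_rate(marker_measurement(ph$AIA_feed, ph$AIA_digesta,
                                              ph$ADF_feed, ph$ADF_digesta,
                                              fiber_kind = "ADF"))
  expect_equal(ndfd, ph$NDFD, tolerance = 1e-12)
  expect_equal(adfd, ph$ADFD, tolerance = 1e-12)
  expect_equal(ndfd / 100, unname(co$truth$true_rate_per_sample),
               tolerance = 1e-12)
})

test_that("FCR is negatively linked to the degradation rate", {
  hits <- 0
  for (i in 1:10) {
    co <- generate_cohort(sim_config(n_samples = 100, n_genera = 40,
                                     n_causal_quant = 2, n_causal_binary = 0,
                                     depth_range = c(5000L, 8000L),
                                     fcr_slope = -0.1, fcr_noise_sd = 0.2,
                                     seed = 100 + i))
    r <- cor(co$phenotype$NDFD, co$phenotype$FCR, method = "spearman")
    hits <- hits + (r < -0.40)
  }
  expect_gte(hits, 8)
})

test_that("a null cohort produces calibrated Spearman false-positive rates", {
  n_hits <- 0L
  n_tests <- 0L
  for (i in 1:30) {
    co <- generate_cohort(sim_config(n_samples = 80, n_genera = 60,
                                     n_causal_quant = 0, n_causal_binary = 0,
                                     depth_range = c(4000L, 6000L),
                                     seed = 400 + i))
    y <- stats::setNames(co$phenotype$NDFD, co$phenotype$sample_id)
    scr <- correlation_screen(normalize_to_min_depth(co$abundance), y)
    n_hits <- n_hits + sum(scr$p < 0.01, na.rm = TRUE)
    n_tests <- n_tests + sum(!is.na(scr$p))
  }
  rate <- n_hits / n_tests
  expect_gt(rate, 0.002)
  expect_lt(rate, 0.022)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genera = 3, n_causal_quant = 3,
                          n_causal_binary = 1), "n_genera")
  expect_error(sim_config(depth_range = c(0L, 10L)), "depth_range")
  expect_error(sim_config(prevalence_range = c(0, 1)), "prevalence_range")
  expect_error(sim_config(n_causal_quant = 7, quant_r2 = 0.15), "< 1")
})
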