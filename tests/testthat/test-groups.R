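test_that("outlier trimming drops values beyond mean +/- 2 SD", {
  v <- c(rep(10, 9), 30)        # mean 12, sample SD ~6.32, bounds ~[-0.65, 24.65]
  keep <- trim_outliers(v)
  expect_equal(keep, c(rep(TRUE, 9), FALSE))
  expect_true(all(trim_outliers(rep(4, 5))))
  expect_true(all(trim_outliers(c(1, 2, 3, 4, 5))))
})

test_that("extreme groups take the top and bottom n after trimming", {
  v <- stats::setNames(1:30, sprintf("a%02d", 1:30))
  g <- extreme_groups(v, n = 10, sd_multiplier = Inf)
  expect_setequal(g$high_ids, sprintf("a%02d", 21:30))
  expect_setequal(g$low_ids, sprintf("a%02d", 1:10))
  expect_length(g$excluded_ids, 0)

  expect_error(extreme_groups(stats::setNames(rnorm(19), letters[1:19]),
                              n = 10, sd_multiplier = Inf), "at least 20")
})

test_that("ties straddling the cut are resolved by sample ID", {
  v <- stats::setNames(c(5, 4, 3, 3, 3, 2, 1, 0), letters[1:8])
  g <- extreme_groups(v, n = 2, sd_multiplier = Inf)
  expect_equal(g$high_ids, c("a", "b"))
  g2 <- extreme_groups(stats::setNames(c(5, 4, 4, 4, 1, 0), letters[1:6]),
                       n = 2, sd_multiplier = Inf)
  expect_equal(g2$high_ids, c("a", "b"))   # 'b' beats 'c','d' on ID order
})

test_that("trimming is applied before ranking", {
  v <- stats::setNames(c(rep(10, 20), 11:16, 100), sprintf("s%02d", 1:27))
  g <- extreme_groups(v, n = 3, sd_multiplier = 2)
  expect_equal(g$excluded_ids, "s27")       # the 100 is outside mean + 2 SD
  expect_false("s27" %in% g$high_ids)
})

test_that("the pooled t-test matches the textbook hand computation", {
  r <- group_ttest(c(5, 6, 7), c(1, 2, 3))
  # means 6 and 2, pooled variance 1, t = 4 / sqrt(2/3)
  expect_equal(r$t, 4 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * stats::pt(-4 / sqrt(2 / 3), 4), tolerance = 1e-10)
})

test_that("degenerate group comparisons follow the documented conventions", {
  same <- group_ttest(c(3, 3, 3), c(3, 3, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  sep <- group_ttest(c(5, 5, 5), c(1, 1, 1))
  expect_equal(sep$t, Inf)
  expect_equal(sep$p, .Machine$double.xmin)

  ident <- group_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})

test_that("Welch and Student variants diverge under unequal variances", {
  set.seed(6)
  a <- rnorm(10, 1, 4)
  b <- rnorm(25, 0, 0.5)
  st <- group_ttest(a, b, "student")
  we <- group_ttest(a, b, "welch")
  expect_false(isTRUE(all.equal(st$df, we$df)))
  expect_equal(we$p, stats::t.test(a, b)$p.value)
})

test_that("group overlap counts shared members", {
  mk <- function(hi, lo) structure(list(high_ids = hi, low_ids = lo),
                                   class = "group_assignment")
  a <- mk(sprintf("s%d", 1:10), sprintf("s%d", 21:30))
  expect_equal(group_overlap(a, a), c(high = 10L, low = 10L))
  b <- mk(sprintf("s%d", 41:50), sprintf("s%d", 61:70))
  expect_equal(unname(group_overlap(a, b)), c(0L, 0L))
  c3 <- mk(sprintf("s%d", 4:13), sprintf("s%d", 24:33))
  expect_equal(group_overlap(a, c3), c(high = 7L, low = 7L))
})

test_that("group comparison flags planted contrasts on a cohort", {
  co <- small_cohort(seed = 8, n = 80, G = 25)
  ph <- co$phenotype
  y <- stats::setNames(ph$NDFD, ph$sample_id)
  g <- extreme_groups(y, n = 10)
  traits <- as.matrix(ph[, c("FCR", "ADFI")])
  rownames(traits) <- ph$sample_id
  cmp <- group_comparison(traits, g, alpha = 0.05)
  fcr <- cmp[cmp$feature == "FCR", ]
  expect_lt(fcr$mean_high, fcr$mean_low)   # efficient animals degrade more

  expect_error(group_comparison(traits[1:40, ], g), "absent")
})
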