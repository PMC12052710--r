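make_counts <- function(m) {
  dimnames(m) <- list(sprintf("s%d", seq_len(nrow(m))),
                      sprintf("g%d", seq_len(ncol(m))))
  composition_matrix(m, "raw_counts")
}

test_that("depth normalization scales every sample to the minimum total", {
  x <- make_counts(matrix(c(60, 40, 120, 80), 2, byrow = TRUE))
  nx <- normalize_to_min_depth(x)
  expect_equal(unname(rowSums(nx)), c(100, 100))
  expect_equal(unname(nx["s2", ]), c(60, 40))

  # equal totals: identity
  y <- make_counts(matrix(c(10, 20, 15, 15), 2, byrow = TRUE))
  expect_equal(unclass(normalize_to_min_depth(y))[, ],
               unclass(y)[, ])

  # scale factors 1, 2/3, 1/3 for totals 50, 75, 150
  z <- make_counts(matrix(c(50, 0, 25, 50, 100, 50), 3, byrow = TRUE))
  nz <- normalize_to_min_depth(z)
  expect_equal(unname(unclass(nz)[, 1] / unclass(z)[, 1]), c(1, 2 / 3, 1 / 3))
  expect_equal(unname(rowSums(nz)), rep(50, 3))
})

test_that("normalization preserves within-sample proportions", {
  set.seed(42)
  x <- make_counts(matrix(rpois(200, 30) + 1, 10, 20))
  nx <- normalize_to_min_depth(x)
  expect_equal(unclass(nx)[, ] / rowSums(nx), unclass(x)[, ] / rowSums(x),
               tolerance = 1e-12)
})

test_that("empty samples are rejected", {
  x <- make_counts(matrix(c(1, 2, 0, 0), 2, byrow = TRUE))
  expect_error(normalize_to_min_depth(x), "s2")
})

test_that("prevalence counts strictly positive cells", {
  x <- make_counts(matrix(c(1, 0, 1,
                            2, 0, 1,
                            3, 0, 1,
                            0, 0, 1,
                            0, 0, 1), 5, byrow = TRUE))
  expect_equal(unname(prevalence(x)), c(0.6, 0, 1))
  expect_error(prevalence(clr_transform(make_counts(matrix(1:4, 2)))),
               "clr")
})

test_that("CLR matches the hand-computed log-ratio values", {
  x <- make_counts(matrix(c(2, 1, 1), 1))
  cl <- clr_transform(x, pseudocount = 1e-9)
  # proportions (1/2, 1/4, 1/4); geometric mean 2^(-5/3)
  expect_equal(unname(unclass(cl)[1, ]),
               c(2 / 3 * log(2), -1 / 3 * log(2), -1 / 3 * log(2)),
               tolerance = 1e-6)
  # uniform row maps to zero
  u <- clr_transform(make_counts(matrix(c(5, 5, 5, 5), 1)), 0.5)
  expect_equal(unname(unclass(u)[1, ]), rep(0, 4))
})

test_that("CLR rows sum to zero for many random compositions", {
  set.seed(7)
  x <- make_counts(matrix(rpois(10000 * 12, 5), 10000, 12))
  x <- composition_matrix(unclass(x)[, ] + 0, "raw_counts")
  cl <- clr_transform(x, 0.5)
  expect_lt(max(abs(rowSums(cl))), 1e-10)
})

test_that("CLR validates inputs", {
  x <- make_counts(matrix(1:4, 2))
  expect_error(clr_transform(x, 0), "positive")
  expect_error(clr_transform(clr_transform(x), 0.5), "raw")
})

test_that("principal components reproduce the two-point hand case", {
  m <- matrix(c(-1, 1, 1, -1), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("g1", "g2")))
  cl <- composition_matrix(m, "clr")     # rows sum to zero by construction
  sc <- principal_components(cl, 1)
  expect_equal(abs(unname(sc[, 1])), c(sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(sum(sc[, 1]), 0, tolerance = 1e-12)
})

test_that("PC scores are orthogonal and recover the total variance", {
  set.seed(11)
  x <- make_counts(matrix(rpois(40 * 8, 20) + 1, 40, 8))
  cl <- clr_transform(x)
  sc <- principal_components(cl, 3)
  expect_lt(abs(sum(sc[, 1] * sc[, 2])), 1e-8)
  expect_lt(abs(sum(sc[, 1] * sc[, 3])), 1e-8)

  # component variances sum to the total at full rank (CLR rank is 7 here),
  # and never exceed it below full rank
  full <- principal_components(cl, 7)
  total <- sum(apply(unclass(cl)[, ], 2, var))
  expect_equal(sum(apply(full, 2, var)), total, tolerance = 1e-8)
  expect_lte(sum(apply(principal_components(cl, 3), 2, var)), total + 1e-8)
})

test_that("principal_components validates k", {
  x <- clr_transform(make_counts(matrix(rpois(40, 9) + 1, 5, 8)))
  expect_error(principal_components(x, 0), "positive")
  expect_error(principal_components(x, 5), "smaller")
})
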