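test_that("bland_altman matches hand arithmetic and degenerate cases", {
  p <- paired_measurements(1:3, c(1, 2, 3), c(2, 2, 5))
  ba <- bland_altman(p)
  expect_equal(ba$bias, -1)
  expect_equal(ba$sd, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1 - 1.96 * sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(ba$loa_high, -1 + 1.96 * sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(ba$loa_ci_halfwidth, 1.96 * sqrt(3 / 3) * sqrt(2 / 3),
               tolerance = 1e-9)
  expect_length(ba$outlier_ids, 0)

  same <- bland_altman(paired_measurements(1:4, c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(same$bias, 0)
  expect_equal(same$sd, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))
})

test_that("missing values are excluded pairwise", {
  p <- paired_measurements(1:5, c(1, NA, 3, 4, 6), c(1, 2, NA, 4, 5))
  ba <- bland_altman(p)
  expect_equal(ba$n, 3L)
  expect_equal(unname(ba$differences), c(0, 0, 1))
  expect_error(bland_altman(paired_measurements(1:3, c(1, NA, NA), c(1, 2, 3))),
               "complete pairs")
})

test_that("outliers are flagged beyond the clinical threshold", {
  p <- paired_measurements(letters[1:4], c(0, 10, 3, -9), c(0, 2, 1, -2))
  ba <- bland_altman(p, outlier_threshold = 5)
  expect_setequal(ba$outlier_ids, c("b", "d"))
})

test_that("mean_rater averages element-wise and propagates missingness", {
  expect_equal(mean_rater(-33.3, -30.5), -31.9)
  expect_equal(mean_rater(c(1, 2), c(1, 2)), c(1, 2))
  expect_true(is.na(mean_rater(c(1, NA), c(1, 2))[2]))
  expect_error(mean_rater(1:3, 1:2), "length")
})

test_that("landmark discrepancy is the per-landmark Euclidean distance", {
  a <- list(crp = c(0, 0, 0), styloid = c(1, 2, 2))
  b <- list(crp = c(3, 4, 0), styloid = c(1, 2, 2))
  d <- landmark_discrepancy(a, b)
  expect_equal(unname(d[["crp"]]), 5)
  expect_equal(unname(d[["styloid"]]), 0)
  set.seed(2)
  for (i in 1:5) {
    p <- stats::rnorm(3); q <- stats::rnorm(3)
    d <- landmark_discrepancy(list(x = p), list(x = q))
    expect_equal(unname(d), sqrt(sum((p - q)^2)))
  }
})

test_that("axis differences are undirected and bounded by 90 degrees", {
  expect_equal(axis_angle_difference(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(axis_angle_difference(c(0, 0, 1),
                                     c(0, sin(5 * pi / 180), cos(5 * pi / 180))),
               5, tolerance = 1e-9)
  expect_equal(axis_angle_difference(c(0, 0, 1), c(0, 0, -1)), 0)
})

test_that("the packaged tables load with their printed shape", {
  t1 <- measurement_table("malunited")
  t2 <- measurement_table("healthy")
  expect_equal(dim(t1), c(16L, 9L))
  expect_equal(dim(t2), c(16L, 7L))
  expect_equal(sum(is.na(t1$vt_2d)), 1L)
  expect_equal(sum(is.na(t2$vt_2d)), 3L)
})

test_that("summarize_table reproduces the descriptive and bias rows", {
  s <- summarize_table("malunited")
  row <- function(df, col) df[df$column == col, ]
  expect_equal(row(s$mean_sd, "vt_2d")$mean, -15.5, tolerance = 0.05)
  expect_equal(row(s$mean_sd, "vt_2d")$n, 15L)
  expect_equal(row(s$mean_sd, "vt_2d")$sd, 14.0, tolerance = 0.05)
  expect_equal(row(s$delta_2d, "vt_auto")$bias, 2.0, tolerance = 0.05)
  expect_equal(row(s$delta_2d, "vt_auto")$sd, 3.8, tolerance = 0.05)
  # a constant column has zero spread
  const <- data.frame(id = 1:4, vt_2d = c(1, 1, 1, 1), vt_auto = c(2, 2, 2, 2))
  sc <- summarize_table(const)
  expect_equal(sc$mean_sd$sd[1], 0)
  expect_equal(sc$delta_2d$sd, 0)
})
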