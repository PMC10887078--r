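test_that("ROI means honor the validity mask", {
  m <- parametric_map(rep(4.2, 10), c(2, 5), "%")
  lab <- rep(c(1, 2), each = 5)
  r <- roi_mean(m, lab, 2)
  expect_equal(r$mean, 4.2)
  expect_equal(r$sd, 0)
  expect_equal(r$n, 5)
  vals <- c(1, 2, 3, 4, NA, NA, 7, 8, 9, 10)
  m2 <- parametric_map(vals, c(2, 5), "%", valid = is.finite(vals))
  r2 <- roi_mean(m2, rep(1, 10), 1)
  expect_equal(r2$n, 8)
  expect_equal(r2$mean, mean(vals, na.rm = TRUE))
  m3 <- parametric_map(rep(NA_real_, 10), c(2, 5), "%",
                       valid = rep(FALSE, 10))
  expect_error(roi_mean(m3, rep(1, 10), 1), "no valid voxels")
})

test_that("phantom ROI means equal the generator ground truth", {
  ph <- synthetic_phantom(shape = c(32, 32), hippo_fraction = 9e-4,
                          seed = 3)
  m <- parametric_map(as.vector(ph$t1_map), ph$shape, "ms",
                      valid = as.vector(ph$label_image > 0))
  r <- roi_mean(m, ph$label_image, c(2, 3))
  expect_lt(abs(r$mean - mean(ph$t1_map[ph$label_image %in% c(2, 3)])),
            1e-6)
})

test_that("the t-test matches the hand-computed pooled-variance oracle", {
  cmp <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  o <- pooled_t_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$statistic, o$t, tolerance = 1e-10)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p_value, o$p, tolerance = 1e-10)
  expect_lt(abs(cmp$statistic - (-3.674)), 1e-3)
  expect_lt(abs(cmp$p_value - 0.0214), 1e-3)
})

test_that("pooled t agrees with the oracle on random tables", {
  set.seed(55)
  for (i in 1:10) {
    x <- rnorm(sample(4:12, 1), 10, 2)
    y <- rnorm(sample(4:12, 1), 11, 3)
    cmp <- compare_groups(c(x, y), rep(c("a", "b"), c(length(x), length(y))))
    o <- pooled_t_oracle(x, y)
    expect_equal(cmp$statistic, o$t, tolerance = 1e-10)
    expect_equal(cmp$p_value, o$p, tolerance = 1e-10)
  }
})

test_that("identical groups give t = 0 and p = 1", {
  cmp <- compare_groups(c(5, 6, 7, 5, 6, 7), rep(c("a", "b"), each = 3))
  expect_equal(cmp$statistic, 0, tolerance = 1e-12)
  expect_equal(cmp$p_value, 1, tolerance = 1e-12)
})

test_that("swapping group labels negates t and preserves p", {
  x <- c(3.1, 4.2, 3.8, 4.4)
  y <- c(5.0, 5.3, 4.9, 5.6)
  g <- rep(c("a", "b"), each = 4)
  c1 <- compare_groups(c(x, y), g)
  c2 <- compare_groups(c(y, x), g)
  expect_equal(c1$statistic, -c2$statistic, tolerance = 1e-12)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
})

test_that("a common affine transform leaves the statistic unchanged", {
  set.seed(8)
  x <- rnorm(8, 4, 1); y <- rnorm(8, 5, 1)
  g <- rep(c("a", "b"), each = 8)
  c1 <- compare_groups(c(x, y), g)
  c2 <- compare_groups(c(2.5 * x + 7, 2.5 * y + 7), g)
  expect_equal(c1$statistic, c2$statistic, tolerance = 1e-10)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-10)
})

test_that("degenerate and malformed group inputs are rejected", {
  expect_error(compare_groups(1:6, rep("a", 6)), "two groups")
  expect_error(compare_groups(c(1, 2), c("a", "b")), "at least 2")
  expect_error(compare_groups(rep(1, 6), rep(c("a", "b"), each = 3)),
               "zero variance")
})

test_that("normality screen and Welch switch are reported", {
  set.seed(12)
  x <- rnorm(12, 5, 0.5); y <- rnorm(12, 4, 1.1)
  cmp <- compare_groups(c(x, y), rep(c("ctl", "fst"), each = 12),
                        var_equal = FALSE)
  expect_match(cmp$method, "Welch")
  expect_true(all(is.finite(cmp$normality_p)))
  expect_true(all(cmp$normality_p >= 0 & cmp$normality_p <= 1))
})
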