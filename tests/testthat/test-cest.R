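sch <- acquisition_schedule()
water <- water_pool()
pool6 <- glu_pool(proton_fraction = 6e-4)

wassr_series <- function(b0, f = 6e-4, noise_sd = 0, seed = 1) {
  z <- simulate_zspectrum(glu_pool(f), water, sch, b0_shift = b0,
                          offsets = sch$wassr_offsets,
                          power = sch$wassr_power)
  if (noise_sd > 0) {
    set.seed(seed)
    z <- pmax(z + rnorm(length(z), 0, noise_sd), 0)
  }
  single_voxel_series(z, sch$wassr_offsets)
}

test_that("WASSR center finding recovers imposed shifts", {
  m0 <- fit_wassr_b0(wassr_series(0))
  expect_true(m0$valid)
  expect_lt(abs(m0$values), 0.005)
  m <- fit_wassr_b0(wassr_series(0.12))
  expect_true(m$valid)
  expect_lt(abs(m$values - 0.12), 0.01)
  m2 <- fit_wassr_b0(wassr_series(-0.31))
  expect_lt(abs(m2$values + 0.31), 0.01)
})

test_that("shifts beyond the search range are flagged, not guessed", {
  m <- fit_wassr_b0(wassr_series(0.75))
  expect_false(m$valid)
  expect_true(is.na(m$values))
})

test_that("WASSR rejects sparse or asymmetric grids", {
  s <- wassr_series(0.1)
  short <- zspectrum_series(s$data[, 1:5, drop = FALSE], s$offsets[1:5],
                            s$reference, c(1, 1))
  expect_error(fit_wassr_b0(short), "at least 7")
  skew <- zspectrum_series(s$data[, 1:20, drop = FALSE], s$offsets[1:20],
                           s$reference, c(1, 1))
  expect_error(fit_wassr_b0(skew), "symmetric")
  expect_s3_class(fit_wassr_b0(skew, allow_asymmetric = TRUE),
                  "parametric_map")
})

test_that("double-angle identities give the textbook B1 values", {
  s30 <- 100
  m1 <- compute_b1_map(s30, 2 * s30 * cos(30 * pi / 180), c(1, 1))
  expect_equal(m1$values, 1.0, tolerance = 1e-9)
  m2 <- compute_b1_map(s30, 2 * s30 * cos(36 * pi / 180), c(1, 1))
  expect_equal(m2$values, 1.2, tolerance = 1e-9)
  # division by zero inside the mask invalidates the voxel
  m3 <- compute_b1_map(c(0, 100), c(50, 160), c(1, 2))
  expect_false(m3$valid[1])
  expect_true(m3$valid[2])
})

test_that("a simulated flip-angle pair recovers the B1 field exactly", {
  ph <- synthetic_phantom(shape = c(24, 24), seed = 11)
  an <- simulate_animal(ph, sch, noise_sd = 0, seed = 2,
                        components = "b1")
  m <- compute_b1_map_from_pair(an$b1_pair)
  brain <- as.vector(ph$label_image > 0)
  err <- abs(m$values - as.vector(ph$b1_scale_map))[m$valid & brain]
  expect_lt(max(err), 1e-3)
})

test_that("identity correction reproduces the input spectrum", {
  z <- simulate_zspectrum(pool6, water, sch)
  s <- single_voxel_series(z, sch$cest_offsets)
  zc <- correct_zspectrum(s, uniform_fields(), target_offsets = c(-3, 3),
                          b1_method = "none")
  expect_lt(abs(zc$data[1] - z[sch$cest_offsets == -3]), 1e-6)
  expect_lt(abs(zc$data[2] - z[sch$cest_offsets == 3]), 1e-6)
})

test_that("B0 correction restores the unshifted asymmetry", {
  z0 <- simulate_zspectrum(pool6, water, sch, b0_shift = 0)
  zs <- simulate_zspectrum(pool6, water, sch, b0_shift = 0.3)
  ref <- 100 * (z0[sch$cest_offsets == -3] - z0[sch$cest_offsets == 3]) /
    z0[sch$cest_offsets == -3]
  s <- single_voxel_series(zs, sch$cest_offsets)
  zc <- correct_zspectrum(s, uniform_fields(b0 = 0.3), b1_method = "none")
  got <- 100 * (zc$data[1] - zc$data[2]) / zc$data[1]
  expect_lt(abs(got - ref), 0.05)
})

test_that("B1 lookup correction maps off-nominal contrast to nominal", {
  lut <- build_b1_lookup(glu_pool(6e-4), water, sch)
  z0 <- simulate_zspectrum(pool6, water, sch, b1_scale = 1)
  ref <- 100 * (z0[sch$cest_offsets == -3] - z0[sch$cest_offsets == 3]) /
    z0[sch$cest_offsets == -3]
  for (b1 in c(0.9, 1.1)) {
    zb <- simulate_zspectrum(pool6, water, sch, b1_scale = b1)
    s <- single_voxel_series(zb, sch$cest_offsets)
    zc <- correct_zspectrum(s, uniform_fields(b1 = b1), b1_lookup = lut)
    got <- 100 * (zc$data[1] - zc$data[2]) / zc$data[1]
    expect_lt(abs(got - ref), 0.1)
  }
})

test_that("GluCEST map implements the printed asymmetry formula", {
  s <- zspectrum_series(matrix(c(0.60, 0.57), 1), c(-3, 3), 1, c(1, 1))
  m <- compute_glucest_map(s)
  expect_equal(m$values, 5.0, tolerance = 1e-12)
  s2 <- zspectrum_series(matrix(c(0.55, 0.55), 1), c(-3, 3), 1, c(1, 1))
  expect_equal(compute_glucest_map(s2)$values, 0, tolerance = 1e-12)
  expect_error(compute_glucest_map(
    zspectrum_series(matrix(c(0.6, 0.5), 1), c(-2, 2), 1, c(1, 1))),
    "-3/\\+3")
})

test_that("the GluCEST map is invariant to global intensity scaling", {
  z <- simulate_zspectrum(pool6, water, sch)
  s1 <- zspectrum_series(matrix(z, 1), sch$cest_offsets, 1, c(1, 1))
  s2 <- zspectrum_series(matrix(z * 730, 1), sch$cest_offsets, 730, c(1, 1))
  zc1 <- correct_zspectrum(s1, uniform_fields(), b1_method = "none")
  zc2 <- correct_zspectrum(s2, uniform_fields(), b1_method = "none")
  expect_equal(compute_glucest_map(zc1)$values,
               compute_glucest_map(zc2)$values, tolerance = 1e-10)
})

test_that("tiny -3 ppm denominators are flagged, not divided", {
  s <- zspectrum_series(matrix(c(0.005, 0.001), 1), c(-3, 3), 1, c(1, 1))
  m <- compute_glucest_map(s)
  expect_false(m$valid)
})

test_that("MTRasym at 3 ppm matches the map on a uniform ROI", {
  z <- simulate_zspectrum(pool6, water, sch)
  nv <- 6
  s <- zspectrum_series(matrix(rep(z, each = nv), nv), sch$cest_offsets,
                        rep(1, nv), c(2, 3))
  curve <- mtr_asymmetry_curve(s, labels = rep(1, nv), roi = 1)
  zc <- correct_zspectrum(s, uniform_fields(nvox = nv, shape = c(2, 3)),
                          b1_method = "none")
  m <- compute_glucest_map(zc)
  expect_lt(abs(100 * curve$mtr_asym[curve$offset == 3] - mean(m$values)),
            1e-9)
  expect_error(mtr_asymmetry_curve(s, labels = rep(1, nv), roi = 9),
               "empty")
})

test_that("the asymmetry curve peaks near the amine resonance", {
  z <- simulate_zspectrum(glu_pool(2e-3), water, sch)
  s <- single_voxel_series(z, sch$cest_offsets)
  curve <- mtr_asymmetry_curve(s, labels = 1, roi = 1)
  pk <- curve$offset[which.max(curve$mtr_asym)]
  expect_gte(pk, 2.5)
  expect_lte(pk, 3.5)
})
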