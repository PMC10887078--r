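sch <- acquisition_schedule()
water <- water_pool()

test_that("pool-free spectra are symmetric and carry zero asymmetry", {
  z <- simulate_zspectrum(glu_pool(proton_fraction = 0), water, sch,
                          b0_shift = 0)
  off <- sch$cest_offsets
  for (d in off[off > 0]) {
    zp <- z[which(abs(off - d) < 1e-12)]
    zm <- z[which(abs(off + d) < 1e-12)]
    expect_lt(abs(zm - zp), 1e-9)
  }
  s <- single_voxel_series(z, off)
  curve <- mtr_asymmetry_curve(s, labels = 1, roi = 1)
  expect_true(all(abs(curve$mtr_asym) < 1e-9))
})

test_that("vanishing saturation power leaves the water signal at unity", {
  z <- simulate_zspectrum(glu_pool(proton_fraction = 0.001), water, sch,
                          power = 0)
  expect_true(all(abs(z - 1) < 1e-9))
})

test_that("Z-values stay within [0, 1] across power, B0 and B1 settings", {
  for (pw in c(0.05, 1, 3.6, 8)) {
    for (b0 in c(-0.3, 0, 0.25)) {
      z <- simulate_zspectrum(glu_pool(proton_fraction = 0.002), water, sch,
                              b0_shift = b0, b1_scale = 1.2, power = pw)
      expect_true(all(z >= 0 & z <= 1 + 1e-12))
    }
  }
})

test_that("finite-duration evolution matches the steady-state oracle", {
  sch_long <- acquisition_schedule(sat_duration = 30000)
  pools <- glu_pool(proton_fraction = 0.001)
  for (b1 in c(1, 0.9)) {
    z <- simulate_zspectrum(pools, water, sch_long, b0_shift = 0.1,
                            b1_scale = b1)
    zo <- bm_steady_state_oracle(sch_long$cest_offsets, pools, water,
                                 sch_long, b0_shift = 0.1, b1_scale = b1)
    expect_lt(max(abs(z - zo)), 1e-6)
  }
})

test_that("three-pool simulation also matches the oracle", {
  mt <- pool_parameters(chemical_shift = -2.4, exchange_rate = 30,
                        proton_fraction = 0.05, t1 = 1.0, t2 = 1e-5)
  pools <- list(glu_pool(proton_fraction = 0.001), mt)
  sch_long <- acquisition_schedule(sat_duration = 30000)
  z <- simulate_zspectrum(pools, water, sch_long)
  zo <- bm_steady_state_oracle(sch_long$cest_offsets, pools, water, sch_long)
  expect_lt(max(abs(z - zo)), 1e-6)
})

test_that("GluCEST contrast is strictly increasing in the pool fraction", {
  fr <- seq(0, 0.01, length.out = 9)
  ct <- vapply(fr, function(f)
    glucest:::forward_glucest_percent(f, list(glu_pool()), water, sch),
    numeric(1))
  expect_true(all(diff(ct) > 0))
  expect_equal(ct[1], 0, tolerance = 1e-9)
})

test_that("invalid pool parameters and negative power are rejected", {
  expect_error(pool_parameters(3, -5, 0.001, 1, 0.01), "exchange_rate")
  expect_error(pool_parameters(3, 5500, 0.5, 1, 0.01), "proton_fraction")
  expect_error(pool_parameters(3, 5500, 0.001, -1, 0.01), "positive")
  expect_error(simulate_zspectrum(glu_pool(), water, sch, power = -1),
               "power")
  bad <- glu_pool()
  bad$t2 <- NaN
  expect_error(simulate_zspectrum(bad, water, sch), "finite")
})

test_that("calibration inverts the forward contrast map", {
  f <- calibrate_contrast(5.02)
  achieved <- glucest:::forward_glucest_percent(f, list(glu_pool()), water,
                                                sch)
  expect_lt(abs(achieved - 5.02), 0.01)
  expect_identical(calibrate_contrast(0), 0)
  expect_lt(calibrate_contrast(3.67), f)
  expect_error(calibrate_contrast(99.9, upper = 0.01), "not achievable")
})
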