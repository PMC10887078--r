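sch <- acquisition_schedule()

series_from <- function(signal, axis, kind, nvox = 1, selective = NULL) {
  relaxation_series(matrix(signal, nvox, length(axis), byrow = TRUE),
                    axis, kind, c(1, nvox), selective = selective)
}

test_that("T1 recovery from the six printed TRs is exact when noiseless", {
  tr <- sch$tr_list
  y <- 1000 * (1 - 1 * exp(-tr / 1800))
  f <- fit_t1_vtr(series_from(y, tr, "TR"))
  expect_true(f$converged)
  expect_lt(abs(f$maps$t1$values - 1800) / 1800, 1e-3)
  expect_lt(abs(f$maps$i0$values - 1000) / 1000, 1e-3)
  expect_lt(abs(f$maps$c$values - 1), 1e-3)
})

test_that("fully relaxed signals are flagged as T1-unidentifiable", {
  tr <- sch$tr_list
  y <- 1000 * (1 - exp(-tr / 30)) # T1 << all TRs
  f <- fit_t1_vtr(series_from(y, tr, "TR"))
  expect_false(f$converged)
  expect_true(is.na(f$maps$t1$values))
})

test_that("T1 Monte-Carlo at 1 percent noise is accurate to 2 percent", {
  tr <- sch$tr_list
  nv <- 200
  set.seed(77)
  clean <- 1000 * (1 - exp(-tr / 1800))
  dat <- matrix(rep(clean, each = nv), nv) +
    matrix(rnorm(nv * length(tr), 0, 10), nv)
  f <- fit_t1_vtr(relaxation_series(dat, tr, "TR", c(10, 20)))
  expect_gt(mean(f$converged), 0.98)
  expect_lt(abs(median(f$maps$t1$values, na.rm = TRUE) - 1800) / 1800, 0.02)
})

test_that("two-point T2 reduces to the closed form", {
  y <- c(1000, 1000 * exp(-140 / 60))
  f <- fit_t2_msme(series_from(y, c(10, 150), "TE"))
  expect_equal(f$maps$t2$values, 60, tolerance = 1e-6)
})

test_that("noiseless multi-echo T2 is recovered almost exactly", {
  te <- sch$te_list
  y <- 850 * exp(-te / 60)
  f <- fit_t2_msme(series_from(y, te, "TE"))
  expect_lt(abs(f$maps$t2$values - 60) / 60, 1e-4)
  # zero decay: unidentifiable
  f2 <- fit_t2_msme(series_from(rep(500, length(te)), te, "TE"))
  expect_false(f2$converged)
  # all-zero voxel: flagged
  f3 <- fit_t2_msme(series_from(rep(0, length(te)), te, "TE"))
  expect_false(f3$converged)
})

test_that("two-point ADC reduces to the log-ratio closed form", {
  f <- fit_adc(series_from(c(1000, 367.88), c(0, 1000), "b"))
  expect_equal(f$maps$adc$values, log(1000 / 367.88) / 1000,
               tolerance = 1e-9)
  expect_equal(f$maps$adc$values, 1.0e-3, tolerance = 1e-4)
})

test_that("noiseless seven-b ADC is exact and degenerate designs error", {
  b <- sch$b_values
  y <- 1200 * exp(-b * 8e-4)
  f <- fit_adc(series_from(y, b, "b"))
  expect_lt(abs(f$maps$adc$values - 8e-4) / 8e-4, 1e-6)
  expect_error(fit_adc(series_from(c(1, 1), c(500, 500), "b")),
               "degenerate|increasing")
  # non-positive samples are dropped pointwise
  y2 <- y; y2[4] <- 0
  f2 <- fit_adc(series_from(y2, b, "b"))
  expect_lt(abs(f2$maps$adc$values - 8e-4) / 8e-4, 1e-6)
})

test_that("log-linear initializer agrees with the refined fit", {
  te <- sch$te_list
  y <- 900 * exp(-te / 48)
  ll <- lm(log(y) ~ te, weights = y^2)
  t2_init <- -1 / coef(ll)[2]
  f <- fit_t2_msme(series_from(y, te, "TE"))
  expect_lt(abs(f$maps$t2$values - t2_init) / t2_init, 0.005)
})

test_that("FAIR CBF follows the T1-difference arithmetic", {
  ti <- sch$ti_list
  mk <- function(t1) 1000 * (1 - 2 * exp(-ti / t1))
  s <- series_from(c(mk(1600), mk(1800)), c(ti, ti), "TI",
                   selective = rep(c(TRUE, FALSE), each = length(ti)))
  f <- fit_fair_cbf(s, lambda = 0.9)
  # hand-computed: 0.9 * (1/1600 - 1/1800) * 6e6 = 375
  expect_lt(abs(f$maps$cbf$values - 375), 1)
  # no perfusion effect: zero CBF
  s0 <- series_from(c(mk(1700), mk(1700)), c(ti, ti), "TI",
                    selective = rep(c(TRUE, FALSE), each = length(ti)))
  expect_lt(abs(fit_fair_cbf(s0)$maps$cbf$values), 1e-6)
  expect_error(fit_fair_cbf(series_from(mk(1700), ti, "TI")), "flag")
})

test_that("relaxometry fits are invariant to global intensity scaling", {
  tr <- sch$tr_list
  y <- 1000 * (1 - 0.96 * exp(-tr / 1500))
  f1 <- fit_t1_vtr(series_from(y, tr, "TR"))
  f2 <- fit_t1_vtr(series_from(y * 37, tr, "TR"))
  expect_equal(f1$maps$t1$values, f2$maps$t1$values, tolerance = 1e-6)
  expect_equal(f2$maps$i0$values / f1$maps$i0$values, 37, tolerance = 1e-6)
})

test_that("noiseless phantom series invert to the ground-truth maps", {
  ph <- synthetic_phantom(shape = c(16, 16), seed = 21)
  an <- simulate_animal(ph, sch, noise_sd = 0, seed = 3,
                        components = c("t1", "t2", "adc", "fair"))
  brain <- as.vector(ph$label_image > 0)
  ft1 <- fit_t1_vtr(an$t1)
  expect_lt(max(abs(ft1$maps$t1$values - as.vector(ph$t1_map))[brain] /
                  as.vector(ph$t1_map)[brain]), 1e-3)
  ft2 <- fit_t2_msme(an$t2)
  expect_lt(max(abs(ft2$maps$t2$values - as.vector(ph$t2_map))[brain] /
                  as.vector(ph$t2_map)[brain]), 1e-3)
  fadc <- fit_adc(an$adc)
  expect_lt(max(abs(fadc$maps$adc$values - as.vector(ph$adc_map))[brain] /
                  as.vector(ph$adc_map)[brain]), 1e-3)
  fcbf <- fit_fair_cbf(an$fair)
  expect_lt(max(abs(fcbf$maps$cbf$values - as.vector(ph$cbf_map))[brain] /
                  as.vector(ph$cbf_map)[brain]), 0.01)
})
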