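basis <- default_basis()
truth <- default_concentrations()

test_that("zero concentrations give a flat spectrum", {
  sp <- synthesize_spectrum(truth * 0, basis, noise_sd = 0)
  expect_true(all(abs(sp$intensity) < 1e-12))
})

test_that("a single metabolite synthesizes proportionally to its basis", {
  sp <- synthesize_spectrum(c(NAA = 3.2), basis, noise_sd = 0)
  expect_equal(sp$intensity, 3.2 * as.numeric(basis[, "NAA"]),
               tolerance = 1e-12)
})

test_that("noiseless mixtures are recovered essentially exactly", {
  sp <- synthesize_spectrum(truth, basis, noise_sd = 0)
  fit <- fit_linear_combination(sp, basis)
  got <- setNames(fit$concentration, fit$metabolite)[names(truth)]
  expect_lt(max(abs(got - truth) / truth), 1e-3)
})

test_that("recovery is unbiased for arbitrary nonnegative truths", {
  set.seed(31)
  for (i in 1:3) {
    cc <- truth * runif(length(truth), 0.3, 2)
    sp <- synthesize_spectrum(cc, basis, noise_sd = 0)
    fit <- fit_linear_combination(sp, basis)
    got <- setNames(fit$concentration, fit$metabolite)[names(cc)]
    expect_lt(max(abs(got - cc) / pmax(cc, 0.1)), 1e-3)
  }
})

test_that("water scaling cancels the instrument gain", {
  sp1 <- synthesize_spectrum(truth, basis, noise_sd = 0, gain = 1)
  sp2 <- synthesize_spectrum(truth, basis, noise_sd = 0, gain = 57.3)
  f1 <- fit_linear_combination(sp1, basis)
  f2 <- fit_linear_combination(sp2, basis)
  expect_equal(f1$concentration, f2$concentration, tolerance = 1e-8)
})

test_that("a polynomial baseline does not corrupt the estimates", {
  sp <- synthesize_spectrum(truth, basis, noise_sd = 0,
                            baseline_coefs = c(0.4, -0.2, 0.3))
  fit <- fit_linear_combination(sp, basis, baseline_order = 2)
  got <- setNames(fit$concentration, fit$metabolite)[names(truth)]
  expect_lt(max(abs(got - truth) / truth), 0.02)
})

test_that("noise calibrated for 5 percent CRLB yields unbiased Glu means", {
  cc <- truth
  cc["Glu"] <- 6.56
  ns <- mrs_noise_for_relative_sd(cc, basis, "Glu", 0.05)
  ests <- vapply(1:10, function(s) {
    sp <- synthesize_spectrum(cc, basis, noise_sd = ns, seed = 1000 + s)
    fit <- fit_linear_combination(sp, basis)
    fit$concentration[fit$metabolite == "Glu"]
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 6.56), 3 * se + 1e-6)
  # empirical spread should be on the order of the 5 percent target
  expect_lt(sd(ests) / 6.56, 0.12)
})

test_that("unknown metabolites and collinear bases are rejected by name", {
  expect_error(synthesize_spectrum(c(Foo = 1), basis), "Foo")
  dup <- cbind(basis, basis[, "Glu"])
  colnames(dup)[ncol(dup)] <- "GluCopy"
  attr(dup, "ppm") <- attr(basis, "ppm")
  class(dup) <- "mrs_basis"
  sp <- synthesize_spectrum(truth, basis, noise_sd = 0)
  expect_error(fit_linear_combination(sp, dup), "Glu.*GluCopy|collinear")
})

test_that("the reported relative SD tracks the linear-model covariance", {
  cc <- truth
  ns <- mrs_noise_for_relative_sd(cc, basis, "Glu", 0.05)
  sp <- synthesize_spectrum(cc, basis, noise_sd = ns, seed = 4)
  fit <- fit_linear_combination(sp, basis)
  rel <- fit$rel_sd_percent[fit$metabolite == "Glu"]
  expect_gt(rel, 1)
  expect_lt(rel, 15)
})
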