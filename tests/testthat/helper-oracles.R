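# Independent oracles, deliberately separate from the package internals.

# Closed-form steady state of the linearized coupled-pool system under CW
# irradiation: Mss = -A^{-1} b, assembled here in plain R from the textbook
# equations. The package's simulator propagates the finite-duration
# solution in compiled code; for long saturation the two must agree.
bm_steady_state_oracle <- function(offsets_ppm, pools, water, schedule,
                                   b0_shift = 0, b1_scale = 1,
                                   power = schedule$sat_power) {
  if (inherits(pools, "pool_parameters")) pools <- list(pools)
  f0 <- schedule$field_hz_per_ppm
  w1 <- 2 * pi * 42.577 * power * b1_scale
  np <- length(pools)
  d <- 3 * (np + 1)
  vapply(offsets_ppm, function(off) {
    A <- matrix(0, d, d)
    b <- numeric(d)
    ka <- sum(vapply(pools, function(p) p$exchange_rate * p$proton_fraction,
                     numeric(1)))
    dw <- 2 * pi * f0 * (b0_shift - off)
    r1a <- 1 / water$t1; r2a <- 1 / water$t2
    A[1, 1] <- -r2a - ka; A[1, 2] <- -dw
    A[2, 1] <- dw; A[2, 2] <- -r2a - ka; A[2, 3] <- w1
    A[3, 2] <- -w1; A[3, 3] <- -r1a - ka
    b[3] <- r1a
    for (p in seq_len(np)) {
      i <- 3 * p + 1
      pp <- pools[[p]]
      k <- pp$exchange_rate; f <- pp$proton_fraction
      dp <- 2 * pi * f0 * (b0_shift + pp$chemical_shift - off)
      r1 <- 1 / pp$t1; r2 <- 1 / pp$t2
      A[i, i] <- -r2 - k; A[i, i + 1] <- -dp
      A[i + 1, i] <- dp; A[i + 1, i + 1] <- -r2 - k; A[i + 1, i + 2] <- w1
      A[i + 2, i + 1] <- -w1; A[i + 2, i + 2] <- -r1 - k
      for (cc in 0:2) {
        A[1 + cc, i + cc] <- A[1 + cc, i + cc] + k
        A[i + cc, 1 + cc] <- A[i + cc, 1 + cc] + k * f
      }
      b[i + 2] <- r1 * f
    }
    solve(A, -b)[3]
  }, numeric(1))
}

# pooled-variance two-sample t from first principles
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# single-voxel z-spectrum wrapped as a series
single_voxel_series <- function(z, offsets, s0 = 1) {
  zspectrum_series(matrix(pmax(z, 0) * s0, 1), offsets, s0, c(1, 1))
}

# uniform synthetic field maps for single-voxel tests
uniform_fields <- function(b0 = 0, b1 = 1, nvox = 1, shape = c(1, nvox)) {
  field_maps(parametric_map(rep(b0, nvox), shape, "ppm"),
             parametric_map(rep(b1, nvox), shape, "relative"))
}
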