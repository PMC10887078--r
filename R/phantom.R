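# Digital phantom: a single 2-D slice with an elliptical "brain" and two
# elliptical hippocampal ROIs, carrying ground-truth parameter images from
# which every acquisition is forward-generated.

ROI_BACKGROUND <- 0L
ROI_BRAIN <- 1L
ROI_HIPPO_LEFT <- 2L
ROI_HIPPO_RIGHT <- 3L

# smooth low-order polynomial random field on [-1,1]^2, peak |f| = amplitude
smooth_field <- function(shape, amplitude) {
  x <- matrix(seq(-1, 1, length.out = shape[1]), shape[1], shape[2])
  y <- matrix(seq(-1, 1, length.out = shape[2]), shape[1], shape[2],
              byrow = TRUE)
  cf <- rnorm(6)
  f <- cf[1] * x + cf[2] * y + cf[3] * x * y +
    cf[4] * (x^2 - 1 / 3) + cf[5] * (y^2 - 1 / 3) + cf[6] * (x^2 - y^2)
  if (max(abs(f)) < .Machine$double.eps) return(f * 0)
  amplitude * f / max(abs(f))
}

in_ellipse <- function(shape, cx, cy, rx, ry) {
  x <- matrix(seq(-1, 1, length.out = shape[1]), shape[1], shape[2])
  y <- matrix(seq(-1, 1, length.out = shape[2]), shape[1], shape[2],
              byrow = TRUE)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

#' Build a ground-truth digital phantom
#'
#' Lays out a single-slice 2-D phantom: an elliptical brain containing
#' disjoint left and right hippocampal ROIs, with per-voxel ground-truth
#' maps for the glutamate pool fraction, T1, T2, ADC, CBF, the static-field
#' offset (B0, ppm) and the relative transmit field (B1). B0 and B1 are
#' smooth random fields, reproducible from `seed`. The label image stands
#' in for manual ROI delineation: 0 background, 1 brain, 2 left
#' hippocampus, 3 right hippocampus.
#'
#' @param shape Image grid, e.g. `c(64, 64)`.
#' @param hippo_fraction Glutamate pool proton fraction inside both
#'   hippocampal ROIs (typically from [calibrate_contrast()]).
#' @param brain_fraction Fraction elsewhere in the brain.
#' @param glu_concentration Hippocampal glutamate concentration, umol/g
#'   (used by the MRS forward model).
#' @param t1_ms,t2_ms,adc,cbf Brain-tissue ground truth (ms, ms, mm^2/s,
#'   mL/100g/min); hippocampal values may differ via `hippo_scale`.
#' @param hippo_scale Multiplicative tweak of relaxometry truth inside the
#'   hippocampus (length-4: T1, T2, ADC, CBF).
#' @param b0_amplitude Peak |B0| offset, ppm (must stay within the WASSR
#'   search range, <= 0.8).
#' @param b1_amplitude Peak deviation of relative B1 from 1.
#' @param seed Integer seed for the random field draws.
#' @return An object of class `synthetic_phantom`.
#' @export
synthetic_phantom <- function(shape = c(64, 64), hippo_fraction = 0.001,
                              brain_fraction = 0.0008,
                              glu_concentration = 7.133,
                              t1_ms = 1900, t2_ms = 45, adc = 7.5e-4,
                              cbf = 120,
                              hippo_scale = c(0.97, 1.05, 0.95, 0.85),
                              b0_amplitude = 0.3, b1_amplitude = 0.08,
                              seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 8L))
  if (b0_amplitude > 0.8)
    stop("b0_amplitude exceeds the WASSR search range (0.8 ppm)")
  set.seed(as.integer(seed))

  brain <- in_ellipse(shape, 0, 0, 0.85, 0.72)
  hip_l <- in_ellipse(shape, -0.38, 0.18, 0.21, 0.15) & brain
  hip_r <- in_ellipse(shape, 0.38, 0.18, 0.21, 0.15) & brain
  if (!any(hip_l) || !any(hip_r)) stop("phantom too small for hippocampal ROIs")
  labels <- matrix(ROI_BACKGROUND, shape[1], shape[2])
  labels[brain] <- ROI_BRAIN
  labels[hip_l] <- ROI_HIPPO_LEFT
  labels[hip_r] <- ROI_HIPPO_RIGHT
  hip <- hip_l | hip_r

  fmap <- matrix(0, shape[1], shape[2])
  fmap[brain] <- brain_fraction
  fmap[hip] <- hippo_fraction
  cmap <- matrix(0, shape[1], shape[2])
  cmap[brain] <- glu_concentration * 0.85
  cmap[hip] <- glu_concentration

  mk <- function(base, scale) {
    m <- matrix(0, shape[1], shape[2])
    m[brain] <- base
    m[hip] <- base * scale
    m
  }
  b0 <- smooth_field(shape, b0_amplitude)
  b0[!brain] <- 0
  b1 <- 1 + smooth_field(shape, b1_amplitude)
  b1[!brain] <- 1

  structure(list(shape = as.integer(shape),
                 label_image = labels,
                 glu_fraction_map = fmap,
                 glu_concentration_map = cmap,
                 t1_map = mk(t1_ms, hippo_scale[1]),
                 t2_map = mk(t2_ms, hippo_scale[2]),
                 adc_map = mk(adc, hippo_scale[3]),
                 cbf_map = mk(cbf, hippo_scale[4]),
                 b0_offset_map = b0,
                 b1_scale_map = b1,
                 seed = as.integer(seed)),
            class = "synthetic_phantom")
}

#' @export
print.synthetic_phantom <- function(x, ...) {
  cat("<synthetic_phantom> ", paste(x$shape, collapse = " x "),
      ", brain voxels: ", sum(x$label_image >= ROI_BRAIN),
      ", hippocampus L/R: ", sum(x$label_image == ROI_HIPPO_LEFT), "/",
      sum(x$label_image == ROI_HIPPO_RIGHT), "\n", sep = "")
  invisible(x)
}

#' Forward-simulate one animal's acquisitions from a phantom
#'
#' Generates the requested series by running the Bloch-McConnell model and
#' the closed-form relaxometry signal equations voxel by voxel on the
#' phantom's ground-truth maps, then adds seeded Gaussian noise of standard
#' deviation `noise_sd * s0` to every frame (high-SNR magnitude
#' approximation). Background voxels carry zero signal.
#'
#' @param phantom A [synthetic_phantom()].
#' @param schedule An [acquisition_schedule()].
#' @param pools,water Exchange model shared by all animals; the first
#'   pool's fraction is taken per voxel from the phantom.
#' @param noise_sd Noise standard deviation as a fraction of S0.
#' @param components Subset of `c("cest", "wassr", "b1", "t1", "t2", "adc",
#'   "fair", "mrs")`.
#' @param s0 Equilibrium signal amplitude in brain voxels.
#' @param basis,mrs_noise_sd MRS basis and absolute noise level used when
#'   `"mrs"` is requested.
#' @param inversion_factor FAIR inversion efficiency factor (2 = complete).
#' @param lambda Blood-brain partition coefficient, mL/g (FAIR truth link).
#' @param seed Integer seed for the noise draws.
#' @return Named list of series objects plus the phantom as `$truth`.
#' @export
simulate_animal <- function(phantom, schedule = acquisition_schedule(),
                            pools = glu_pool(), water = water_pool(),
                            noise_sd = 0.01,
                            components = c("cest", "wassr", "b1"),
                            s0 = 1000, basis = NULL, mrs_noise_sd = 0,
                            inversion_factor = 2, lambda = 0.9, seed = 1L) {
  set.seed(as.integer(seed))
  shape <- phantom$shape
  nv <- prod(shape)
  brain <- as.vector(phantom$label_image >= ROI_BRAIN)
  frac <- as.vector(phantom$glu_fraction_map)[brain]
  b0 <- as.vector(phantom$b0_offset_map)[brain]
  b1 <- as.vector(phantom$b1_scale_map)[brain]
  ref <- numeric(nv); ref[brain] <- s0
  noisy <- function(m) {
    if (noise_sd > 0) m + matrix(rnorm(length(m), 0, noise_sd * s0),
                                 nrow(m), ncol(m)) else m
  }
  expand <- function(zb, noff) {
    full <- matrix(0, nv, noff)
    full[brain, ] <- zb * s0
    full
  }
  out <- list()

  if ("cest" %in% components) {
    zb <- simulate_zspectrum_image(pools, water, schedule, frac, b0, b1,
                                   offsets = schedule$cest_offsets,
                                   power = schedule$sat_power)
    m <- noisy(expand(zb, length(schedule$cest_offsets)))
    m[m < 0] <- 0
    out$cest <- zspectrum_series(m, schedule$cest_offsets, ref, shape,
                                 mask = brain)
  }
  if ("wassr" %in% components) {
    zb <- simulate_zspectrum_image(pools, water, schedule, frac, b0, b1,
                                   offsets = schedule$wassr_offsets,
                                   power = schedule$wassr_power)
    m <- noisy(expand(zb, length(schedule$wassr_offsets)))
    m[m < 0] <- 0
    out$wassr <- zspectrum_series(m, schedule$wassr_offsets, ref, shape,
                                  mask = brain)
  }
  if ("b1" %in% components) {
    a <- schedule$b1_angles * pi / 180
    pair <- cbind(ref * sin(a[1] * as.vector(phantom$b1_scale_map)),
                  ref * sin(a[2] * as.vector(phantom$b1_scale_map)))
    pair[!brain, ] <- 0
    pair <- noisy(pair)
    out$b1_pair <- list(flip_low = pair[, 1], flip_high = pair[, 2],
                        angles = schedule$b1_angles, shape = shape,
                        mask = brain)
  }
  t1v <- as.vector(phantom$t1_map)
  if ("t1" %in% components) {
    # I(TR) = I0 (1 - C exp(-TR/T1)), C = 1 (saturation recovery)
    m <- outer(seq_len(nv), seq_along(schedule$tr_list), function(i, j)
      ref[i] * (1 - exp(-schedule$tr_list[j] / pmax(t1v[i], 1e-6))))
    m[!brain, ] <- 0
    out$t1 <- relaxation_series(noisy(m), schedule$tr_list, "TR", shape,
                                mask = brain)
  }
  if ("t2" %in% components) {
    t2v <- as.vector(phantom$t2_map)
    m <- outer(seq_len(nv), seq_along(schedule$te_list), function(i, j)
      ref[i] * exp(-schedule$te_list[j] / pmax(t2v[i], 1e-6)))
    m[!brain, ] <- 0
    out$t2 <- relaxation_series(noisy(m), schedule$te_list, "TE", shape,
                                mask = brain)
  }
  if ("adc" %in% components) {
    av <- as.vector(phantom$adc_map)
    m <- outer(seq_len(nv), seq_along(schedule$b_values), function(i, j)
      ref[i] * exp(-schedule$b_values[j] * av[i]))
    m[!brain, ] <- 0
    out$adc <- relaxation_series(noisy(m), schedule$b_values, "b", shape,
                                 mask = brain)
  }
  if ("fair" %in% components) {
    cbfv <- as.vector(phantom$cbf_map)
    r1ns <- 1 / pmax(t1v, 1e-6)                  # 1/ms
    r1sel <- r1ns + cbfv / (lambda * 6e6)        # perfusion shortens T1
    ti <- schedule$ti_list
    sig <- function(r1) outer(seq_len(nv), seq_along(ti), function(i, j)
      ref[i] * (1 - inversion_factor * exp(-ti[j] * r1[i])))
    msel <- sig(r1sel); mns <- sig(r1ns)
    msel[!brain, ] <- 0; mns[!brain, ] <- 0
    out$fair <- relaxation_series(cbind(noisy(msel), noisy(mns)),
                                  c(ti, ti), "TI", shape, mask = brain,
                                  selective = rep(c(TRUE, FALSE), each =
                                                    length(ti)))
  }
  if ("mrs" %in% components) {
    if (is.null(basis)) basis <- default_basis()
    conc <- default_concentrations()
    conc["Glu"] <- max(phantom$glu_concentration_map)
    out$mrs <- synthesize_spectrum(conc, basis, noise_sd = mrs_noise_sd,
                                   seed = sample.int(2^31 - 2, 1))
  }
  out$truth <- phantom
  out
}

# deterministic per-animal sub-seed from one master seed
animal_seed <- function(master, index) {
  as.integer((as.numeric(master) + 104729 * as.numeric(index)) %% 2147483646 + 1)
}

#' Generate a two-group simulated cohort
#'
#' Emulates the study design: two groups of `n_per_group` animals whose
#' hippocampal glutamate levels are set per group, with normal
#' between-animal jitter, each animal carrying its own random B0/B1 fields
#' and measurement noise. Group levels are specified as target GluCEST
#' contrasts (percent) and converted to pool fractions with
#' [calibrate_contrast()], so the generator's ground truth is expressed on
#' the same scale the pipeline measures. Identical seeds reproduce the
#' cohort exactly.
#'
#' @param n_per_group Animals per group (>= 2).
#' @param group_contrast Named list/vector of hippocampal GluCEST targets
#'   in percent, one per group.
#' @param between_sd Named like `group_contrast`: between-animal SD of the
#'   target, percent.
#' @param group_concentration,concentration_sd Hippocampal glutamate
#'   concentration (umol/g) mean and between-animal SD per group, used for
#'   the MRS forward model.
#' @param noise_sd Image noise as a fraction of S0.
#' @param shape Phantom grid.
#' @param components Series to simulate per animal (see
#'   [simulate_animal()]).
#' @param pools,water,schedule Shared forward model.
#' @param brain_contrast GluCEST target for non-hippocampal brain, percent.
#' @param seed Master seed; per-animal seeds are derived by a fixed
#'   splitting rule.
#' @return An object of class `glucest_cohort`: per-animal data with ground
#'   truth, plus the shared model and schedule.
#' @export
generate_cohort <- function(n_per_group = 12,
                            group_contrast = c(control = 5.02, fst = 3.67),
                            between_sd = c(control = 0.44, fst = 0.81),
                            group_concentration = c(control = 7.133,
                                                    fst = 6.560),
                            concentration_sd = c(control = 0.397,
                                                 fst = 0.292),
                            noise_sd = 0.01, shape = c(64, 64),
                            components = c("cest", "wassr", "b1"),
                            pools = glu_pool(), water = water_pool(),
                            schedule = acquisition_schedule(),
                            brain_contrast = 4.0, seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  groups <- names(group_contrast)
  if (is.null(groups) || any(!nzchar(groups)))
    stop("group_contrast must be named by group")
  for (nm in c("between_sd")) {
    miss <- setdiff(groups, names(get(nm)))
    if (length(miss)) stop(nm, " is missing group(s): ",
                           paste(miss, collapse = ", "))
  }
  set.seed(as.integer(seed))
  brain_frac <- calibrate_contrast(brain_contrast, pools, water, schedule)

  animals <- list()
  idx <- 0L
  for (g in groups) {
    targets <- rnorm(n_per_group, group_contrast[[g]], between_sd[[g]])
    targets <- pmax(targets, 0.2)
    concs <- rnorm(n_per_group,
                   if (g %in% names(group_concentration))
                     group_concentration[[g]] else 7,
                   if (g %in% names(concentration_sd))
                     concentration_sd[[g]] else 0)
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      sd_i <- animal_seed(seed, idx)
      frac_i <- calibrate_contrast(targets[i], pools, water, schedule)
      ph <- synthetic_phantom(shape = shape, hippo_fraction = frac_i,
                              brain_fraction = brain_frac,
                              glu_concentration = concs[i], seed = sd_i)
      dat <- simulate_animal(ph, schedule, pools, water, noise_sd,
                             components = components, seed = sd_i + 1L)
      animals[[idx]] <- list(id = sprintf("%s_%02d", g, i), group = g,
                             target_percent = targets[i],
                             glu_fraction = frac_i,
                             glu_concentration = concs[i],
                             data = dat)
    }
  }
  structure(list(animals = animals, groups = groups, seed = as.integer(seed),
                 pools = if (inherits(pools, "pool_parameters")) list(pools)
                         else pools,
                 water = water, schedule = schedule, noise_sd = noise_sd,
                 brain_fraction = brain_frac),
            class = "glucest_cohort")
}

#' @export
print.glucest_cohort <- function(x, ...) {
  cat("<glucest_cohort> ", length(x$animals), " animals in groups: ",
      paste(x$groups, collapse = ", "), "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}
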