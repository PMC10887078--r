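# CEST core: WASSR B0 mapping, double-angle B1 mapping, B0/B1 correction,
# and the MTR-asymmetry GluCEST map.

#' Combine B0 and B1 maps into one field-map object
#'
#' @param b0 [parametric_map()] of per-voxel water-center offsets, ppm.
#' @param b1 [parametric_map()] of per-voxel relative B1.
#' @return An object of class `field_maps` with a joint validity mask.
#' @export
field_maps <- function(b0, b1) {
  stopifnot(inherits(b0, "parametric_map"), inherits(b1, "parametric_map"),
            all(b0$shape == b1$shape))
  structure(list(b0_offset = b0$values, b1_relative = b1$values,
                 valid = b0$valid & b1$valid, shape = b0$shape),
            class = "field_maps")
}

#' Per-voxel B0 mapping from a WASSR series
#'
#' Estimates the water-center frequency in every voxel by the
#' maximum-symmetry-center method: the center c minimizing the weighted
#' squared difference between the voxel's WASSR Z-spectrum and its mirror
#' about c. Each spectrum is first resampled onto a fine grid with
#' shape-preserving cubic interpolation so mirrored points fall on grid
#' nodes; the cost is weighted by saturation depth (1 - Z)^2 so it is
#' dominated by the water dip, evaluated over a candidate grid, and the
#' minimum refined by a three-point parabolic fit. Voxels whose minimum
#' falls on the boundary of the candidate grid, whose mirror overlap
#' misses the dip, or whose fitted center disagrees with the dip location
#' are flagged invalid.
#'
#' @param wassr A [zspectrum_series()] sampling a dense symmetric grid
#'   (protocol default: +/-0.8 ppm in 0.05 ppm steps).
#' @param search Candidate center range, ppm.
#' @param step Candidate grid spacing, ppm (refinement resolves below it).
#' @param allow_asymmetric Permit a non-symmetric offset grid.
#' @return A [parametric_map()] of B0 offsets in ppm.
#' @export
fit_wassr_b0 <- function(wassr, search = c(-0.5, 0.5), step = 0.01,
                         allow_asymmetric = FALSE) {
  o <- wassr$offsets
  if (length(o) < 7) stop("WASSR needs at least 7 offsets, got ", length(o))
  if (!allow_asymmetric && max(abs(sort(o) + rev(sort(o)))) > 1e-6)
    stop("WASSR offset grid is not symmetric about 0; ",
         "set allow_asymmetric = TRUE to override")
  ord <- order(o)
  o <- o[ord]
  z <- z_normalized(wassr)[, ord, drop = FALSE]
  msk <- wassr$mask
  z[!msk, ] <- 0 # harmless placeholder, flagged invalid below

  cand <- seq(search[1], search[2], by = step)
  # resample each voxel onto a fine grid (half the candidate step) with
  # shape-preserving cubic interpolation, so every mirrored point falls on
  # a grid node and the cost carries no interpolation bias
  fs <- step / 2
  g <- seq(o[1], o[length(o)], by = fs)
  vox <- which(msk)
  zf <- matrix(1, length(vox), length(g))
  for (k in seq_along(vox))
    zf[k, ] <- splinefun(o, z[vox[k], ], method = "monoH.FC")(g)
  n <- length(g)
  # saturation-depth weights: the cost must be dominated by the water dip,
  # otherwise mirror overlaps containing only flat wings win spuriously
  wt <- (1 - zf)^2
  wt_total <- rowSums(wt)
  cost <- matrix(Inf, length(vox), length(cand))
  for (j in seq_along(cand)) {
    idx <- seq_len(n)
    midx <- round((2 * cand[j] - 2 * g[1]) / fs) - idx + 2L # index of 2c - g
    keep <- which(midx >= 1L & midx <= n)
    if (length(keep) < 5) next
    num <- rowSums(wt[, keep, drop = FALSE] *
                     (zf[, keep, drop = FALSE] -
                        zf[, midx[keep], drop = FALSE])^2)
    den <- rowSums(wt[, keep, drop = FALSE])
    cj <- num / den
    cj[den < 0.25 * wt_total] <- Inf
    cost[, j] <- cj
  }
  best <- max.col(-cost, ties.method = "first")
  interior <- best > 1 & best < length(cand)
  b0m <- cand[best]
  # parabolic refinement through the three grid points around the minimum
  ii <- which(interior)
  if (length(ii)) {
    cm <- cost[cbind(ii, best[ii] - 1L)]
    c0 <- cost[cbind(ii, best[ii])]
    cp <- cost[cbind(ii, best[ii] + 1L)]
    den <- cm - 2 * c0 + cp
    shift <- ifelse(is.finite(den) & abs(den) > .Machine$double.eps &
                      is.finite(cm) & is.finite(cp),
                    0.5 * (cm - cp) / den, 0)
    b0m[ii] <- b0m[ii] + step * pmax(pmin(shift, 1), -1)
  }
  # the fitted center must sit near the voxel's own saturation dip;
  # shifts beyond the candidate range otherwise alias to interior minima
  dip <- g[max.col(-zf, ties.method = "first")]
  okm <- interior & is.finite(b0m) &
    is.finite(cost[cbind(seq_along(vox), best)]) &
    abs(dip - b0m) <= 0.1
  b0 <- rep(NA_real_, length(msk))
  b0[vox] <- b0m
  valid <- rep(FALSE, length(msk))
  valid[vox] <- okm
  parametric_map(b0, wassr$shape, "ppm", valid = valid)
}

#' Relative B1 map by the double-angle method
#'
#' From two gradient-recalled images at nominal flip angles alpha and
#' 2*alpha, the actual angle is `acos(S(2a) / (2 S(a)))` (the ratio is
#' clamped to `[-1, 1]`); the relative B1 is the actual-to-nominal ratio.
#'
#' @param flip_low Image at the lower nominal angle (per-voxel vector).
#' @param flip_high Image at the doubled angle.
#' @param shape Image grid.
#' @param mask Logical per voxel.
#' @param nominal Lower nominal flip angle, degrees.
#' @return A [parametric_map()] of dimensionless relative B1.
#' @export
compute_b1_map <- function(flip_low, flip_high, shape,
                           mask = rep(TRUE, length(flip_low)), nominal = 30) {
  if (length(flip_low) != length(flip_high))
    stop("flip-angle images differ in size")
  valid <- mask & is.finite(flip_low) & is.finite(flip_high) & flip_low > 0
  ratio <- rep(NA_real_, length(flip_low))
  ratio[valid] <- flip_high[valid] / (2 * flip_low[valid])
  ratio <- pmax(pmin(ratio, 1), -1)
  alpha <- acos(ratio) * 180 / pi
  b1 <- alpha / nominal
  valid <- valid & is.finite(b1) & b1 > 0
  parametric_map(b1, shape, "relative", valid = valid)
}

#' @rdname compute_b1_map
#' @param pair A `b1_pair` list as produced by [simulate_animal()].
#' @export
compute_b1_map_from_pair <- function(pair) {
  compute_b1_map(pair$flip_low, pair$flip_high, pair$shape, pair$mask,
                 nominal = pair$angles[1])
}

#' Precompute the contrast-versus-B1 lookup table
#'
#' Tabulates the forward-model GluCEST contrast as a function of the
#' relative transmit field at a reference pool configuration. B1
#' correction maps an observed contrast at relative B1 `b` to nominal B1
#' by the ratio `L(1)/L(b)` with linear interpolation in `b`.
#'
#' @param pools,water,schedule Forward model (first pool's fraction is the
#'   reference amplitude).
#' @param b1_grid Relative-B1 grid to tabulate.
#' @return A data frame (class `b1_lookup`) with columns `b1`, `contrast`.
#' @export
build_b1_lookup <- function(pools = glu_pool(), water = water_pool(),
                            schedule = acquisition_schedule(),
                            b1_grid = seq(0.5, 1.5, by = 0.05)) {
  if (inherits(pools, "pool_parameters")) pools <- list(pools)
  f <- pools[[1]]$proton_fraction
  if (f <= 0) f <- 0.001
  ct <- vapply(b1_grid, function(b)
    forward_glucest_percent(f, pools, water, schedule, b1_scale = b),
    numeric(1))
  structure(data.frame(b1 = b1_grid, contrast = ct), class =
              c("b1_lookup", "data.frame"))
}

#' B0- and B1-correct a saturation series
#'
#' Per voxel, the offset axis is shifted by the fitted water-center offset
#' and the spectrum is re-sampled at the requested target offsets by cubic
#' spline interpolation (default; a shape-preserving monotone variant is
#' available via `interp` for use near the water dip -- the +/-3 ppm
#' targets sit far from it, where the spline is markedly more accurate). The B1 correction then
#' rescales the asymmetry contrast at each symmetric target pair from the
#' voxel's relative B1 to nominal: with the forward-model lookup
#' (`"lookup"`, default) the contrast is multiplied by `L(1)/L(b1)`; the
#' `"linear"` fallback divides by `b1`; `"none"` skips it. Voxels invalid
#' in either field map, or whose shifted targets leave the sampled range,
#' are flagged invalid.
#'
#' @param z A [zspectrum_series()].
#' @param fields A [field_maps()] object.
#' @param target_offsets Offsets at which the corrected spectrum is
#'   reported, ppm (default the +/-3 ppm pair the GluCEST formula uses).
#' @param b1_method Correction variant (recorded in the result metadata).
#' @param b1_lookup A [build_b1_lookup()] table (required for `"lookup"`).
#' @param interp Spectrum resampling method.
#' @return A corrected [zspectrum_series()] sampled at `target_offsets`.
#' @export
correct_zspectrum <- function(z, fields, target_offsets = c(-3, 3),
                              b1_method = c("lookup", "linear", "none"),
                              b1_lookup = NULL,
                              interp = c("spline", "monotone")) {
  b1_method <- match.arg(b1_method)
  interp <- match.arg(interp)
  spl_method <- if (interp == "spline") "fmm" else "monoH.FC"
  stopifnot(inherits(z, "zspectrum_series"), inherits(fields, "field_maps"))
  if (b1_method == "lookup" && is.null(b1_lookup))
    stop("b1_method = 'lookup' requires a b1_lookup table")
  ord <- order(z$offsets)
  o <- z$offsets[ord]
  nv <- nrow(z$data)
  valid <- z$mask & fields$valid
  out <- matrix(NA_real_, nv, length(target_offsets))
  for (v in which(valid)) {
    want <- target_offsets + fields$b0_offset[v]
    if (any(want < o[1] | want > o[length(o)])) {
      valid[v] <- FALSE
      next
    }
    fun <- splinefun(o, z$data[v, ord], method = spl_method)
    out[v, ] <- fun(want)
  }
  # contrast-level B1 correction on symmetric target pairs
  if (b1_method != "none") {
    pos <- which(target_offsets > 0)
    for (p in pos) {
      m <- which(abs(target_offsets + target_offsets[p]) < 1e-9)
      if (!length(m)) next
      b1v <- fields$b1_relative
      if (b1_method == "lookup") {
        l1 <- approx(b1_lookup$b1, b1_lookup$contrast, xout = 1)$y
        lb <- approx(b1_lookup$b1, b1_lookup$contrast, xout = b1v)$y
        ratio <- l1 / lb
        valid <- valid & is.finite(ratio) & lb > 0
      } else {
        ratio <- 1 / b1v
      }
      vv <- which(valid & is.finite(out[, m[1]]) & out[, m[1]] > 0)
      ct <- (out[vv, m[1]] - out[vv, p]) / out[vv, m[1]]
      out[vv, p] <- out[vv, m[1]] * (1 - ct * ratio[vv])
    }
  }
  res <- zspectrum_series(pmax(out, 0) |> replace_na_zero_outside(valid),
                          target_offsets, z$reference, z$shape, mask = valid)
  attr(res, "b1_method") <- b1_method
  res
}

# zspectrum_series rejects negative/NA data; store zeros outside validity
replace_na_zero_outside <- function(m, valid) {
  m[!valid, ] <- 0
  m[is.na(m)] <- 0
  m
}

#' GluCEST map from a corrected series
#'
#' Applies the asymmetry formula
#' `GluCEST(%) = 100 (M[-3 ppm] - M[+3 ppm]) / M[-3 ppm]`
#' voxel by voxel. Voxels whose -3 ppm signal falls below
#' `denom_eps * S0` are flagged invalid to guard the division.
#'
#' @param z_corrected A corrected [zspectrum_series()] containing samples
#'   at -3.0 and +3.0 ppm.
#' @param denom_eps Denominator guard as a fraction of S0.
#' @return A [parametric_map()] in percent.
#' @export
compute_glucest_map <- function(z_corrected, denom_eps = 0.01) {
  im <- which(abs(z_corrected$offsets + 3) < 1e-6)
  ip <- which(abs(z_corrected$offsets - 3) < 1e-6)
  if (!length(im) || !length(ip))
    stop("corrected series lacks the -3/+3 ppm samples")
  mm <- z_corrected$data[, im[1]]
  mp <- z_corrected$data[, ip[1]]
  valid <- z_corrected$mask & is.finite(mm) & is.finite(mp) &
    mm > denom_eps * z_corrected$reference
  vals <- 100 * (mm - mp) / mm
  parametric_map(vals, z_corrected$shape, "%", valid = valid)
}

#' ROI-averaged MTR asymmetry curve
#'
#' Averages the normalized Z-spectrum over an ROI and evaluates
#' `MTRasym(d) = (M(-d) - M(+d)) / M(-d)` at every positive offset whose
#' mirror is sampled.
#'
#' @param z A [zspectrum_series()].
#' @param labels Integer label image (vector or matrix).
#' @param roi Label code(s) defining the ROI.
#' @return Data frame with columns `offset` (ppm) and `mtr_asym`
#'   (fraction; multiply by 100 for percent).
#' @export
mtr_asymmetry_curve <- function(z, labels, roi) {
  sel <- as.vector(labels) %in% roi & z$mask
  if (!any(sel)) stop("ROI is empty after masking")
  zn <- colMeans(z_normalized(z)[sel, , drop = FALSE])
  o <- z$offsets
  pos <- sort(o[o > 0])
  keep <- vapply(pos, function(p) any(abs(o + p) < 1e-9), logical(1))
  pos <- pos[keep]
  asym <- vapply(pos, function(p) {
    mm <- zn[which.min(abs(o + p))]
    mp <- zn[which.min(abs(o - p))]
    (mm - mp) / mm
  }, numeric(1))
  data.frame(offset = pos, mtr_asym = asym)
}
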