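# Voxelwise relaxometry: variable-TR T1, multi-echo T2, monoexponential
# ADC, and FAIR perfusion from paired inversion-recovery T1 fits.

#' Relaxometry fit result
#'
#' Bundles the per-voxel parameter maps of one fitter with convergence
#' flags and a residual (RMSE) map. Non-converged or degenerate voxels
#' carry NA parameters.
#'
#' @param maps Named list of [parametric_map()] objects.
#' @param converged Logical per voxel.
#' @param residual Numeric per voxel (root-mean-square residual).
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(maps, converged, residual) {
  structure(list(maps = maps, converged = converged, residual = residual),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> maps: ", paste(names(x$maps), collapse = ", "),
      "; converged ", sum(x$converged), "/", length(x$converged),
      " voxels\n", sep = "")
  invisible(x)
}

# Saturation/inversion-recovery engine for one voxel:
# I(t) = i0 (1 - C exp(-t / t1)). Two starts (default and log-linear),
# keep the lower-cost solution. Returns c(i0, C, t1, rmse, converged).
fit_recovery_voxel <- function(y, x, t1_bounds = c(50, 10000),
                               c_bounds = c(0.5, 2.5)) {
  bad <- c(NA, NA, NA, NA, 0)
  if (all(!is.finite(y)) || max(y, na.rm = TRUE) <= 0) return(bad)
  rng <- diff(range(y))
  if (rng <= 1e-4 * max(abs(y)))  # fully relaxed at every t: T1 unidentifiable
    return(bad)
  starts <- list(list(i0 = max(y), C = 1, t1 = median(x)))
  i0h <- 1.02 * max(y)
  w <- 1 - y / i0h
  ok <- which(w > 1e-8)
  if (length(ok) >= 2) {
    ll <- lm(log(w[ok]) ~ x[ok])
    t1l <- -1 / unname(coef(ll)[2])
    cl <- exp(unname(coef(ll)[1]))
    if (is.finite(t1l) && t1l > 0)
      starts <- c(starts, list(list(
        i0 = i0h,
        C = min(max(cl, c_bounds[1]), c_bounds[2]),
        t1 = min(max(t1l, t1_bounds[1]), t1_bounds[2]))))
  }
  if (any(y < 0) && any(y > 0)) {
    # inversion-recovery start from the zero crossing: y = 0 at t0 = T1 ln C
    iz <- which(diff(sign(y)) > 0)[1]
    if (!is.na(iz)) {
      t0 <- x[iz] - y[iz] * (x[iz + 1] - x[iz]) / (y[iz + 1] - y[iz])
      t1z <- min(max(t0 / log(2), t1_bounds[1]), t1_bounds[2])
      i0z <- y[which.max(x)] / max(1 - 2 * exp(-max(x) / t1z), 0.05)
      if (is.finite(i0z) && i0z > 0)
        starts <- c(starts, list(list(i0 = i0z, C = min(2, c_bounds[2]),
                                      t1 = t1z)))
    }
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ i0 * (1 - C * exp(-x / t1)), start = st,
                        lower = c(0, c_bounds[1], t1_bounds[1]),
                        upper = c(Inf, c_bounds[2], t1_bounds[2]),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(bad)
  p <- coef(best$fit)
  c(p[["i0"]], p[["C"]], p[["t1"]], sqrt(best$rss / length(y)), 1)
}

#' T1 mapping from a variable-TR series
#'
#' Per-voxel nonlinear least squares of the saturation-recovery model
#' `I(TR) = I0 (1 - C exp(-TR/T1))`, where C absorbs incomplete
#' magnetization preparation. Each voxel is fitted from two starts (the
#' default initialization and a log-linear estimate) and the lower-cost
#' solution is kept. Voxels whose signal does not vary over TR (fully
#' relaxed at every TR) are unidentifiable and flagged.
#'
#' @param series A [relaxation_series()] with `axis_kind = "TR"` (ms).
#' @param t1_bounds,c_bounds Box constraints for T1 (ms) and C.
#' @return A [fit_result()] with maps `i0`, `c`, `t1`.
#' @export
fit_t1_vtr <- function(series, t1_bounds = c(50, 10000),
                       c_bounds = c(0.5, 2.5)) {
  stopifnot(inherits(series, "relaxation_series"), series$axis_kind == "TR")
  if (length(series$axis_values) < 3) stop("need at least 3 TR points")
  fit_recovery_series(series, t1_bounds, c_bounds, "t1", "ms")
}

fit_recovery_series <- function(series, t1_bounds, c_bounds, pname, punit,
                                data = series$data,
                                axis = series$axis_values) {
  nv <- nrow(data)
  out <- matrix(NA_real_, nv, 5)
  for (v in which(series$mask))
    out[v, ] <- fit_recovery_voxel(data[v, ], axis, t1_bounds, c_bounds)
  conv <- !is.na(out[, 5]) & out[, 5] == 1
  maps <- list(
    i0 = parametric_map(out[, 1], series$shape, "a.u.", valid = conv),
    c = parametric_map(out[, 2], series$shape, "", valid = conv))
  maps[[pname]] <- parametric_map(out[, 3], series$shape, punit, valid = conv)
  fit_result(maps, conv, out[, 4])
}

#' T2 mapping from a multi-echo series
#'
#' Weighted log-linear regression of `log I` on TE initializes a
#' nonlinear least-squares refinement of `I(TE) = I0 exp(-TE/T2)`.
#' All-zero voxels and voxels with no measurable decay (constant signal,
#' T2 effectively infinite) are flagged unidentifiable.
#'
#' @param series A [relaxation_series()] with `axis_kind = "TE"` (ms).
#' @return A [fit_result()] with maps `i0`, `t2`.
#' @export
fit_t2_msme <- function(series) {
  stopifnot(inherits(series, "relaxation_series"), series$axis_kind == "TE")
  if (length(series$axis_values) < 2) stop("need at least 2 TE points")
  fit_decay_series(series, series$axis_values, "t2", "ms", rate = FALSE)
}

#' ADC mapping from a multi-b diffusion series
#'
#' Log-linear fit of `I(b) = I0 exp(-b ADC)` refined by nonlinear least
#' squares. Non-positive samples are excluded pointwise; voxels with
#' fewer than two usable points are flagged.
#'
#' @param series A [relaxation_series()] with `axis_kind = "b"` (s/mm^2),
#'   including a (near-)zero b-value.
#' @return A [fit_result()] with maps `i0`, `adc` (mm^2/s).
#' @export
fit_adc <- function(series) {
  stopifnot(inherits(series, "relaxation_series"), series$axis_kind == "b")
  if (var(series$axis_values) == 0)
    stop("degenerate design: all b-values identical")
  if (length(series$axis_values) < 2) stop("need at least 2 b-values")
  fit_decay_series(series, series$axis_values, "adc", "mm^2/s", rate = TRUE)
}

# Shared monoexponential decay fitter. rate = TRUE parameterizes the decay
# constant directly (ADC); rate = FALSE parameterizes its inverse (T2, ms).
fit_decay_series <- function(series, axis, pname, punit, rate) {
  nv <- nrow(series$data)
  out <- matrix(NA_real_, nv, 4) # i0, param, rmse, converged
  for (v in which(series$mask)) {
    y <- series$data[v, ]
    use <- which(is.finite(y) & y > 0)
    if (length(use) < 2) next
    ll <- lm(log(y[use]) ~ axis[use], weights = y[use]^2)
    slope <- unname(coef(ll)[2])
    i0 <- exp(unname(coef(ll)[1]))
    if (!is.finite(slope) || slope >= -1e-12) next # no decay: unidentifiable
    k0 <- -slope
    fit <- tryCatch(
      minpack.lm::nlsLM(y[use] ~ i0 * exp(-k * axis[use]),
                        start = list(i0 = i0, k = k0),
                        lower = c(0, 0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    p <- coef(fit)
    val <- if (rate) p[["k"]] else 1 / p[["k"]]
    out[v, ] <- c(p[["i0"]], val, sqrt(sum(resid(fit)^2) / length(use)), 1)
  }
  conv <- !is.na(out[, 4]) & out[, 4] == 1
  maps <- list(i0 = parametric_map(out[, 1], series$shape, "a.u.",
                                   valid = conv))
  maps[[pname]] <- parametric_map(out[, 2], series$shape, punit, valid = conv)
  fit_result(maps, conv, out[, 3])
}

#' CBF mapping from a FAIR inversion-recovery pair
#'
#' Fits apparent T1 separately for the slice-selective and non-selective
#' inversion-recovery series (same engine as [fit_t1_vtr()] with TI in
#' place of TR) and quantifies perfusion by the T1-difference model:
#' `CBF = lambda (1/T1_sel - 1/T1_ns) * 6e6` in mL/100g/min with T1 in ms
#' and the blood-brain partition coefficient lambda in mL/g.
#'
#' @param series A [relaxation_series()] with `axis_kind = "TI"` and a
#'   `selective` flag per frame; phase-sensitive (signed) reconstruction
#'   is assumed.
#' @param lambda Partition coefficient, mL/g.
#' @param t1_bounds,c_bounds Passed to the recovery engine.
#' @return A [fit_result()] with maps `cbf`, `t1_sel`, `t1_ns`.
#' @export
fit_fair_cbf <- function(series, lambda = 0.9, t1_bounds = c(50, 10000),
                         c_bounds = c(0.5, 2.5)) {
  stopifnot(inherits(series, "relaxation_series"), series$axis_kind == "TI")
  if (is.null(series$selective))
    stop("FAIR series needs a selective/non-selective frame flag")
  sel <- series$selective
  if (sum(sel) < 5 || sum(!sel) < 5)
    stop("need at least 5 TIs in each labeling condition")
  f_sel <- fit_recovery_series(series, t1_bounds, c_bounds, "t1", "ms",
                               data = series$data[, sel, drop = FALSE],
                               axis = series$axis_values[sel])
  f_ns <- fit_recovery_series(series, t1_bounds, c_bounds, "t1", "ms",
                              data = series$data[, !sel, drop = FALSE],
                              axis = series$axis_values[!sel])
  conv <- f_sel$maps$t1$valid & f_ns$maps$t1$valid
  cbf <- lambda * (1 / f_sel$maps$t1$values - 1 / f_ns$maps$t1$values) * 6e6
  maps <- list(cbf = parametric_map(cbf, series$shape, "mL/100g/min",
                                    valid = conv),
               t1_sel = f_sel$maps$t1, t1_ns = f_ns$maps$t1)
  fit_result(maps, conv, pmax(f_sel$residual, f_ns$residual))
}
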