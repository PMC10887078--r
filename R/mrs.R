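# Simplified linear-combination MRS quantification: nonnegative
# least-squares superposition of metabolite basis spectra plus a smooth
# polynomial baseline, with water-reference scaling to umol/g. This is a
# deliberately plain linear-combination fitter (no regularized lineshape
# estimation or Voigt refinement); forward and inverse share the basis, so
# calibration constants cancel in recovery studies.

#' 1H MR spectrum container
#'
#' @param ppm Chemical-shift axis, ppm (descending, spectroscopy
#'   convention).
#' @param intensity Spectral intensity per point, arbitrary units.
#' @param water_reference_area Integrated area of the unsuppressed water
#'   reference, same arbitrary units.
#' @param acquisition Optional list of TR/TE in ms.
#' @return An object of class `mr_spectrum`.
#' @export
mr_spectrum <- function(ppm, intensity, water_reference_area,
                        acquisition = list(tr = 5000, te = 16.3)) {
  if (length(ppm) != length(intensity))
    stop("ppm and intensity differ in length")
  if (any(diff(ppm) >= 0) && any(diff(ppm) <= 0))
    stop("ppm axis must be monotone")
  if (water_reference_area <= 0) stop("water reference area must be positive")
  structure(list(ppm = ppm, intensity = intensity,
                 water_reference_area = water_reference_area,
                 acquisition = acquisition),
            class = "mr_spectrum")
}

#' @export
print.mr_spectrum <- function(x, ...) {
  cat("<mr_spectrum> ", length(x$ppm), " points, ",
      round(min(x$ppm), 2), "-", round(max(x$ppm), 2), " ppm\n", sep = "")
  invisible(x)
}

#' Default chemical-shift axis
#'
#' @param from,to,step Axis limits and spacing, ppm (descending).
#' @return Numeric ppm axis covering the 4.3-0.3 ppm fit window.
#' @export
mrs_ppm_axis <- function(from = 4.6, to = 0.0, step = 0.008) {
  seq(from, to, by = -abs(step))
}

# line tables: position (ppm) and proton count per modeled moiety;
# simplified literature positions for the major 1H resonances
mrs_line_table <- function() {
  list(
    NAA = cbind(c(2.01, 2.49, 2.67), c(3, 1, 1)),
    Cr  = cbind(c(3.03, 3.91), c(3, 2)),
    Cho = cbind(c(3.19), c(9)),
    Glu = cbind(c(2.04, 2.12, 2.35, 3.75), c(1, 1, 2, 1)),
    Gln = cbind(c(2.14, 2.45, 3.77), c(2, 2, 1)),
    mIns = cbind(c(3.52, 3.61, 4.05), c(4, 1, 1)),
    Tau = cbind(c(3.25, 3.42), c(2, 2))
  )
}

#' Typical rodent-hippocampus concentrations
#'
#' Starting values (umol/g) for the synthetic forward model.
#' @return Named numeric vector.
#' @export
default_concentrations <- function() {
  c(NAA = 5.5, Cr = 5.5, Cho = 1.2, Glu = 7.1, Gln = 3.0,
    mIns = 4.5, Tau = 5.0)
}

# pseudo-Voigt line, unit area, FWHM in ppm
pv_line <- function(ppm, center, fwhm, mix = 0.5) {
  g <- fwhm / (2 * sqrt(2 * log(2)))
  lor <- (fwhm / (2 * pi)) / ((ppm - center)^2 + (fwhm / 2)^2)
  gau <- exp(-(ppm - center)^2 / (2 * g^2)) / (g * sqrt(2 * pi))
  mix * lor + (1 - mix) * gau
}

#' Simulated metabolite basis set
#'
#' Builds per-metabolite model spectra as sums of pseudo-Voigt lines at
#' fixed literature positions, each metabolite normalized to unit
#' integrated area per proton, on a shared ppm grid. Line positions are
#' configuration data, not measurements.
#'
#' @param ppm Shared axis from [mrs_ppm_axis()].
#' @param fwhm Linewidth (FWHM), ppm.
#' @param metabolites Subset of names to include.
#' @return An object of class `mrs_basis`: matrix of basis spectra
#'   (points x metabolites) with `protons` attribute.
#' @export
default_basis <- function(ppm = mrs_ppm_axis(), fwhm = 0.035,
                          metabolites = names(mrs_line_table())) {
  tab <- mrs_line_table()
  unknown <- setdiff(metabolites, names(tab))
  if (length(unknown))
    stop("unknown metabolite(s): ", paste(unknown, collapse = ", "))
  dppm <- abs(mean(diff(ppm)))
  mat <- vapply(metabolites, function(m) {
    lines <- tab[[m]]
    s <- rowSums(vapply(seq_len(nrow(lines)), function(i)
      lines[i, 2] * pv_line(ppm, lines[i, 1], fwhm), numeric(length(ppm))))
    s
  }, numeric(length(ppm)))
  protons <- vapply(metabolites, function(m) sum(tab[[m]][, 2]), numeric(1))
  structure(mat, ppm = ppm, protons = protons, class = "mrs_basis")
}

#' Synthesize a 1H spectrum from known concentrations
#'
#' Forward model for the linear-combination fit: the spectrum is the
#' concentration-weighted sum of basis spectra, optionally convolved with
#' a Gaussian broadening kernel, plus a polynomial baseline and seeded
#' Gaussian noise. The unsuppressed water reference area is set from the
#' configured tissue water concentration, so water scaling in the fit is
#' self-consistent.
#'
#' @param concentrations Named vector, umol/g (names must exist in the
#'   basis).
#' @param basis An `mrs_basis`.
#' @param noise_sd Additive noise SD, intensity units.
#' @param lineshape_broadening Extra Gaussian broadening (FWHM), Hz.
#' @param seed Optional integer seed for the noise draw.
#' @param baseline_coefs Polynomial baseline coefficients (constant
#'   first), or NULL for none.
#' @param water_concentration Tissue water concentration, umol/g.
#' @param gain Arbitrary instrument scale applied to spectrum and water
#'   reference alike.
#' @param field_hz_per_ppm Water frequency, Hz/ppm (converts Hz to ppm).
#' @return An [mr_spectrum()].
#' @export
synthesize_spectrum <- function(concentrations, basis = default_basis(),
                                noise_sd = 0, lineshape_broadening = 0,
                                seed = NULL, baseline_coefs = NULL,
                                water_concentration = 43300, gain = 1,
                                field_hz_per_ppm = 300) {
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  unknown <- setdiff(names(concentrations), colnames(basis))
  if (length(unknown))
    stop("unknown metabolite(s): ", paste(unknown, collapse = ", "))
  ppm <- attr(basis, "ppm")
  s <- as.numeric(basis[, names(concentrations), drop = FALSE] %*%
                    concentrations)
  if (lineshape_broadening > 0) {
    fw <- lineshape_broadening / field_hz_per_ppm    # ppm
    dppm <- abs(mean(diff(ppm)))
    sdpts <- fw / (2 * sqrt(2 * log(2))) / dppm
    half <- ceiling(4 * sdpts)
    k <- exp(-0.5 * ((-half:half) / sdpts)^2)
    k <- k / sum(k)
    n <- length(s)
    spad <- c(rep(s[1], half), s, rep(s[n], half))
    s <- as.numeric(stats::filter(spad, k, sides = 2))[(half + 1):(half + n)]
  }
  if (!is.null(baseline_coefs)) {
    x <- (ppm - mean(ppm)) / (diff(range(ppm)) / 2)
    s <- s + as.numeric(outer(x, seq_along(baseline_coefs) - 1, "^") %*%
                          baseline_coefs)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (noise_sd > 0) s <- s + rnorm(length(s), 0, noise_sd)
  mr_spectrum(ppm, s * gain,
              water_reference_area = 2 * water_concentration * gain)
}

# design matrix for the fit window: basis columns plus signed polynomial
# baseline columns (NNLS handles free-sign baselines via +/- pairs)
mrs_design <- function(basis, ppm, window, baseline_order) {
  w <- which(ppm >= min(window) & ppm <= max(window))
  if (!length(w)) stop("fit window outside the spectral axis")
  B <- basis[w, , drop = FALSE]
  x <- (ppm[w] - mean(ppm[w])) / (diff(range(ppm[w])) / 2)
  P <- outer(x, 0:baseline_order, "^")
  list(idx = w, X = cbind(B, P, -P), nb = ncol(B), np = ncol(P))
}

#' Linear-combination fit of a 1H spectrum
#'
#' Nonnegative least squares of the spectrum over the 4.3-0.3 ppm window
#' against the metabolite basis plus a free-sign polynomial baseline.
#' Basis coefficients are converted to umol/g by water scaling with the
#' unsuppressed water reference; per-metabolite uncertainty is a
#' CRLB-style relative SD from the linear-model covariance.
#'
#' @param spectrum An [mr_spectrum()].
#' @param basis An `mrs_basis` on the same ppm grid.
#' @param window Fit window, ppm.
#' @param baseline_order Polynomial baseline order.
#' @param water_concentration Tissue water concentration, umol/g (must
#'   match the value the water reference was calibrated with).
#' @return Data frame with columns `metabolite`, `concentration`
#'   (umol/g), `rel_sd_percent`.
#' @export
fit_linear_combination <- function(spectrum, basis = default_basis(),
                                   window = c(0.3, 4.3), baseline_order = 2,
                                   water_concentration = 43300) {
  stopifnot(inherits(spectrum, "mr_spectrum"))
  ppm <- attr(basis, "ppm")
  if (length(ppm) != length(spectrum$ppm) ||
      max(abs(ppm - spectrum$ppm)) > 1e-9)
    stop("basis and spectrum must share the same ppm grid")
  d <- mrs_design(basis, ppm, window, baseline_order)
  # collinearity screen on the basis block
  cb <- stats::cor(d$X[, seq_len(d$nb), drop = FALSE])
  diag(cb) <- 0
  if (any(cb > 0.9995)) {
    ij <- which(cb == max(cb), arr.ind = TRUE)[1, ]
    stop("basis spectra are collinear in the fit window: ",
         colnames(basis)[ij[1]], " vs ", colnames(basis)[ij[2]])
  }
  y <- spectrum$intensity[d$idx]
  nn <- pracma::lsqnonneg(d$X, y)
  coefs <- nn$x[seq_len(d$nb)]
  res <- y - as.numeric(d$X %*% nn$x)
  dof <- max(length(y) - ncol(d$X), 1)
  sigma <- sqrt(sum(res^2) / dof)
  xtx <- crossprod(cbind(d$X[, seq_len(d$nb), drop = FALSE],
                         d$X[, d$nb + seq_len(d$np), drop = FALSE]))
  v <- diag(pracma::pinv(xtx))[seq_len(d$nb)]
  scale <- 2 * water_concentration / spectrum$water_reference_area
  conc <- coefs * scale
  rel_sd <- ifelse(coefs > 0, 100 * sigma * sqrt(pmax(v, 0)) / coefs, Inf)
  data.frame(metabolite = colnames(basis),
             concentration = conc,
             rel_sd_percent = rel_sd,
             row.names = NULL)
}

#' Noise level for a target relative uncertainty
#'
#' Computes the additive noise SD at which the linear-model (CRLB-style)
#' relative SD of one metabolite's coefficient equals a target, for a
#' given basis, truth and baseline order. Used to generate spectra whose
#' fit uncertainty matches a stated percentage.
#'
#' @param concentrations Named truth, umol/g.
#' @param basis An `mrs_basis`.
#' @param metabolite Which metabolite the target refers to.
#' @param target_rel Target relative SD (0.05 = 5 percent).
#' @param window,baseline_order As in [fit_linear_combination()].
#' @return Noise SD in intensity units.
#' @export
mrs_noise_for_relative_sd <- function(concentrations,
                                      basis = default_basis(),
                                      metabolite = "Glu",
                                      target_rel = 0.05,
                                      window = c(0.3, 4.3),
                                      baseline_order = 2) {
  ppm <- attr(basis, "ppm")
  d <- mrs_design(basis, ppm, window, baseline_order)
  m <- match(metabolite, colnames(basis))
  if (is.na(m)) stop("unknown metabolite: ", metabolite)
  xtx <- crossprod(cbind(d$X[, seq_len(d$nb), drop = FALSE],
                         d$X[, d$nb + seq_len(d$np), drop = FALSE]))
  v <- diag(pracma::pinv(xtx))[m]
  target_rel * concentrations[[metabolite]] / sqrt(v)
}
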