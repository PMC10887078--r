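---
title: "Models and methods behind glucest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glucest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucest)
```

# What this package computes

Glutamate-weighted CEST (GluCEST) imaging detects glutamate indirectly:
a frequency-selective continuous-wave pulse saturates the amine protons
that resonate about +3 ppm downfield of water, chemical exchange carries
that saturation into the water pool, and the water signal drops. The
GluCEST contrast is the magnetization-transfer-ratio asymmetry evaluated
at the amine offset,

$$\mathrm{GluCEST}(\%) \;=\; 100\,
  \frac{M_{-3\,\mathrm{ppm}} - M_{+3\,\mathrm{ppm}}}{M_{-3\,\mathrm{ppm}}},$$

where both signals are corrected per voxel for static-field (B0) and
transmit-field (B1) inhomogeneity. `glucest` implements that chain for a
7 T rodent protocol — WASSR B0 mapping, double-angle B1 mapping,
spectral correction, asymmetry mapping — together with voxelwise
relaxometry (variable-TR T1, multi-echo T2, monoexponential ADC, FAIR
perfusion), a simplified linear-combination fit of 1H MR spectra, and
left/right hippocampal ROI statistics with a two-group comparison.

Because no scanner data ship with the package, every stage is validated
against a digital phantom whose acquisitions are *forward-simulated*
from known ground truth. The phantom generator is first-class, tested
code: all recovery claims in the test suite are claims about inverting
that generator.

# The Bloch–McConnell forward model

Saturation is modeled with the coupled Bloch–McConnell equations for
water plus one or more exchanging solute pools (star topology: each
solute exchanges with water only). Under continuous-wave irradiation the
system is linear, $\dot M = A M + b$, and the package propagates the
exact finite-duration solution

$$M(t_\mathrm{sat}) = M_\mathrm{ss} + e^{A t_\mathrm{sat}}\,
  (M_0 - M_\mathrm{ss}), \qquad M_\mathrm{ss} = -A^{-1} b,$$

in compiled code (one 6x6 — or $3(n{+}1)$-dimensional — matrix
exponential per voxel and offset). The test suite checks this
propagation against an independently assembled closed-form steady-state
solver written in plain R; the two agree to below $10^{-6}$ once the
saturation is long compared to water $T_1$ (the suite uses 30 s — with
water $T_1 = 1.9$ s, a 1 s pulse is still far from steady state, which
is exactly why the finite-duration solution, not the steady state, is
the production path).

Key defaults, all configurable:

| parameter | default | rationale |
|---|---|---|
| water $T_1$, $T_2$ | 1.9 s, 50 ms | rodent brain parenchyma at 7 T |
| amine shift | +3.0 ppm | glutamate amine resonance |
| amine exchange rate | 2000 s$^{-1}$ | literature-plausible for amine protons; slow enough that the asymmetry curve peaks near the pool resonance at 3.6 uT |
| amine $T_1$, $T_2$ | 1.0 s, 8 ms | typical labile-proton values |
| saturation | 3.6 uT, 1000 ms | the imaging protocol |
| field scale | 300 Hz/ppm | 7 T water frequency |

Amine exchange rates reported in vivo span roughly 2000–7000 s$^{-1}$
depending on pH and temperature; no value is asserted as the study's.
Nothing downstream depends on the absolute choice, because cohort
simulation *calibrates* the pool size against the forward model
(`calibrate_contrast()`): a bracketed root-find returns the proton
fraction whose noiseless, ideally-shimmed spectrum yields a requested
GluCEST percentage. The forward map is strictly increasing in the
fraction over the working range (verified by grid scan), so the
calibration is well posed. Ground truth is thereby expressed in the same
units the pipeline measures, and recovery tests are exact
forward–inverse consistency checks rather than tests of any particular
exchange-physics parameterization.

The readout is treated as a pass-through (instantaneous sampling of
water $M_z$ after saturation); RARE signal evolution, k-space, motion
and partial-volume effects are not modeled. Noise is additive Gaussian
on the magnitude at a stated fraction of $S_0$ — a high-SNR
approximation of Rician statistics.

# The digital phantom and cohort generator

`synthetic_phantom()` lays out a single 2-D slice (matching the
single-slice protocol): an elliptical brain with two disjoint elliptical
hippocampal ROIs (labels: 0 background, 1 brain, 2 left, 3 right
hippocampus), per-voxel ground truth for the glutamate pool fraction,
T1/T2/ADC/CBF, and smooth random B0 (ppm) and relative-B1 fields built
from low-order polynomial surfaces — smooth, shim-like spatial
structure, reproducible from a seed. The B0 amplitude (default 0.3 ppm,
capped at the 0.8 ppm WASSR range) and B1 deviation (default 8 %) are
chosen as typical shim/coil inhomogeneity scales for a surface-coil
rodent setup.

`generate_cohort()` emulates the study design: two groups of 12 animals,
hippocampal GluCEST targets drawn per animal from
$\mathcal N(\text{group mean}, \text{between-animal SD})$, each animal's
pool fraction calibrated to its target, fresh B0/B1 fields and fresh
measurement noise per animal. One master seed drives everything through
a fixed per-animal splitting rule, so identical seeds reproduce the
cohort bit for bit. The default image noise is 1 % of $S_0$ (SNR 100),
a realistic figure for an averaged RARE acquisition at 7 T.

What the generator deliberately does *not* emulate: magnetization
transfer from semisolids and NOE contributions (a third pool is
supported but off by default), Rician noise floors, motion, atlas-based
ROI placement, and any realistic spatial texture within tissue classes.
Passing recovery tests therefore demonstrate correctness of the
*analysis chain* under the stated forward model, not robustness to
everything real data can do.

# Field mapping and correction

**B0 (WASSR).** The water-center offset of each voxel is found by the
maximum-symmetry-center method: the center $c$ minimizing the squared
difference between the low-power Z-spectrum and its mirror about $c$.
Each spectrum is first resampled onto a fine grid (5 mppm) with
shape-preserving monotone cubic interpolation so that mirrored samples
fall on grid nodes — this removes the interpolation bias that otherwise
appears when the true center is misaligned with the 0.05 ppm sampling.
The cost is weighted by saturation depth $(1-Z)^2$, which keeps it
anchored to the water dip (mirror overlaps containing only flat spectral
wings would otherwise win spuriously), evaluated over a candidate grid
(default ±0.5 ppm, 0.01 ppm steps) and refined by a three-point
parabolic fit. A voxel is flagged invalid when its minimum lands on the
candidate boundary, when the mirror overlap misses the dip, or when the
fitted center disagrees with the dip location by more than 0.1 ppm —
shifts beyond the search range alias to spurious interior minima
otherwise, and flagging is preferred to guessing. Noiseless recovery is
better than 0.01 ppm and SNR-50 recovery better than 0.025 ppm — half
the WASSR step size.

**B1 (double angle).** From nominal 30/60 degree images, the actual
flip angle is $\alpha = \arccos\!\big(S(2\alpha)/2S(\alpha)\big)$ (ratio
clamped to $[-1,1]$), and relative B1 is $\alpha/30^\circ$. Division by
zero inside the mask invalidates the voxel.

**Correction.** The offset axis is shifted by $-B_0$ per voxel and the
spectrum re-sampled at ±3 ppm. Resampling uses a cubic spline by
default: the targets sit on the smooth flank of the spectrum far from
the water dip, where the spline's accuracy (about 0.04 percentage points
of contrast at a 0.3 ppm shift on the 0.5 ppm grid) clearly beats the
shape-preserving monotone variant (about 0.11); the monotone variant
remains available (`interp = "monotone"`) for resampling near the dip.
B1 correction is applied on the contrast: a precomputed
contrast-versus-B1 lookup from the forward model maps the observed
asymmetry at the voxel's B1 to nominal B1 by the ratio $L(1)/L(b_1)$
(linear interpolation in $b_1$). Whether the original analysis corrected
the contrast or the raw spectrum is not stated anywhere we could check;
the choice is recorded in the result metadata, and a simple
divide-by-$b_1$ fallback (`b1_method = "linear"`) is provided. Voxels
invalid in any field map stay invalid in the GluCEST map — no silent
fill. The $-3$ ppm denominator is guarded at $0.01\,S_0$.

# Relaxometry

All fitters are per-voxel least squares with explicit degeneracy flags:

* **T1 (variable TR):** $I = I_0(1 - C e^{-TR/T_1})$ with $C$ free per
  voxel (absorbs incomplete magnetization preparation), bounds
  $T_1 \in [50, 10000]$ ms, $C \in [0.5, 2.5]$. Fits start from both a
  default and a log-linear initialization (plus a zero-crossing-based
  start when the series is signed, i.e. inversion recovery) and keep the
  lower-cost solution. Signals that do not vary over TR are flagged
  unidentifiable rather than fitted.
* **T2 / ADC:** weighted log-linear fit as initializer, nonlinear
  refinement of $I_0 e^{-TE/T_2}$ / $I_0 e^{-b\,\mathrm{ADC}}$;
  non-positive samples excluded pointwise; no-decay voxels flagged.
* **FAIR CBF:** apparent T1 fitted separately for slice-selective and
  non-selective inversion series, then
  $\mathrm{CBF} = \lambda\,(1/T_{1,\mathrm{sel}} - 1/T_{1,\mathrm{ns}})
  \times 6\times10^6$ mL/100 g/min with T1 in ms and
  $\lambda = 0.9$ mL/g. The vendor-side reconstruction used originally
  is not public; this standard T1-difference model is a documented
  stand-in, and phase-sensitive (signed) reconstruction is assumed.

Convergence tolerance is $10^{-10}$ on the cost with at most 200
iterations. No Rician bias correction is applied (high-SNR assumption)
and no multi-exponential or multi-compartment variants are offered.

# MRS quantification

The spectral module is deliberately a *simplified* linear-combination
fitter, not a reimplementation of the commercial package used in
practice (no regularized lineshape estimation, no Voigt refinement, no
macromolecule model). Basis spectra for Glu, Gln, NAA, Cr, Cho,
myo-inositol and taurine are sums of pseudo-Voigt lines at fixed
literature positions, each metabolite normalized to unit area per
proton; positions are configuration data, not asserted as any
particular acquisition's basis. The fit is nonnegative least squares
over 4.3–0.3 ppm with a free-sign polynomial baseline (order 2 by
default, implemented as signed column pairs inside the NNLS), and
concentrations come from water scaling with the unsuppressed reference
(tissue water constant 43.3 mol/L-equivalent by default). Because the
synthetic spectra and the fit share the basis and water calibration, the
scaling constants cancel in recovery studies — recovery tests check the
estimator, not the constants. Reported uncertainty is a CRLB-style
relative SD from the linear-model covariance; noise levels for
simulation studies are chosen by inverting that formula
(`mrs_noise_for_relative_sd()`), e.g. for a 5 % relative SD on Glu.

# ROI statistics

ROI means are arithmetic means over valid voxels only; an ROI with no
valid voxels is an error. Imaging measures use the bilateral average
(left + right)/2; the MRS value refers to a single hippocampal voxel
(placed on the right side in the emulated design, to match how the
spectroscopy voxel was positioned). The group comparison is a two-sided
independent two-sample t-test, equal-variance by default (the classic
statistics-package default) with a Welch switch, preceded by a
per-group Kolmogorov–Smirnov normality screen. Since population
parameters are estimated from the sample, the Lilliefors variant is
used — a documented deviation from a plain one-sample KS test, whose
null distribution would be wrong here. Normality p-values are reported
as NA below n = 5, where the screen is meaningless. No multiplicity
correction is applied across maps, matching the emulated analysis.

# Problem sizes, runtime and numerical choices

Defaults were chosen so the full corrected pipeline on a 12 + 12 cohort
at 64 x 64 runs in about a minute on one CPU. The replication study
(100 cohorts) uses a spatially down-scaled 16 x 16 phantom; because ROI
noise scales as $\sigma/\sqrt{n_\mathrm{vox}}$, the voxel noise is
scaled by $\sqrt{n_\mathrm{hippo,small}/n_\mathrm{hippo,full}}$ so that
ROI-level measurement noise matches the full-size grid — spatial
resolution is reduced, the statistical conditions are not.

A note on the replication study itself: with group means and SDs of
5.02 ± 0.44 % versus 3.67 ± 0.81 % at n = 12 per group, the
noncentrality of the pooled t-test is about 5.07, which gives a power of
roughly 0.87 for two-sided p < 0.001. A single observed p < 0.001 is
therefore entirely expected, but fewer than 95 % of replicate cohorts
drawn from those same population parameters reach it — the package
reports the replicate p-value distribution honestly rather than tuning
the generator until the bar is met.

Other numerical conventions: voxel coordinates are 0-based column-major
index space (no world/atlas coordinates — registration is out of
scope); all sidecars record units explicitly (ppm, ms, s/mm^2, %,
umol/g, mL/100 g/min); series are NIfTI 4-D with the acquisition axis
last; spectra are two-column tables plus metadata.

# Known limitations

* Two-pool physics by default; semisolid MT and NOE are not in the
  default phantom, so in vivo asymmetry curves will differ from the
  simulated ones at negative offsets.
* The B1 lookup is built at a reference pool amplitude; its ratio
  correction is exact only to the extent the contrast-versus-B1 shape
  is amplitude-independent (a very good approximation in the small-pool
  regime the package operates in).
* The MRS module's absolute units are self-consistent, not
  scanner-calibrated.
* No Bruker/DICOM readers; the real-data path is NIfTI plus JSON
  sidecars.
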