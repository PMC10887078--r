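# glucest

Glutamate-weighted CEST (GluCEST) MRI analysis for 7 T rodent brain
studies, validated end to end against a Bloch–McConnell digital phantom.

## The problem

GluCEST imaging maps cerebral glutamate at high spatial resolution by
saturating the glutamate amine protons (~+3 ppm from water) and reading
out the saturation transferred to water. The contrast is the
magnetization-transfer-ratio asymmetry at the amine offset,

```
GluCEST (%) = 100 · (M[−3 ppm] − M[+3 ppm]) / M[−3 ppm]
```

with both signals corrected per voxel for B0 (via WASSR) and B1 (via a
double-angle flip map). Getting from raw saturation series to a
defensible group comparison involves a chain of voxelwise estimators —
water-center fitting, field correction, asymmetry mapping, relaxometry,
spectroscopy quantification, ROI statistics — each of which can silently
bias the result. This package implements that chain for users analyzing
preclinical CEST studies (or building simulation studies of them), with
every estimator tested against forward-simulated ground truth:

* **`synthetic_phantom()` / `generate_cohort()`** — 2-D digital phantoms
  (brain + left/right hippocampal ROIs) with ground-truth glutamate,
  T1/T2/ADC/CBF, B0 and B1 maps; full two-group cohort simulation with
  seeded noise and between-animal variation, forward-modeled through the
  Bloch–McConnell equations in compiled code.
* **`calibrate_contrast()`** — root-finds the glutamate pool fraction
  that produces a requested GluCEST %, so ground truth lives in the same
  units the pipeline measures.
* **`fit_wassr_b0()`, `compute_b1_map()`, `correct_zspectrum()`,
  `compute_glucest_map()`, `mtr_asymmetry_curve()`** — the corrected
  GluCEST chain.
* **`fit_t1_vtr()`, `fit_t2_msme()`, `fit_adc()`, `fit_fair_cbf()`** —
  voxelwise relaxometry at the protocol's TR/TE/b/TI schedules.
* **`synthesize_spectrum()`, `fit_linear_combination()`** — simplified
  linear-combination 1H-MRS quantification (NNLS + polynomial baseline,
  water scaling).
* **`roi_mean()`, `compare_groups()`, `run_pipeline()`** — ROI
  quantification, Lilliefors normality screen, independent t-test, and
  the cohort-level orchestration.

NIfTI + JSON-sidecar readers/writers (`write_series()`, `read_series()`,
`write_cohort()`, `read_manifest()`) connect the pipeline to on-disk
studies; a thin command-line wrapper lives in `inst/cli/glucest.R`.

## Worked example

Simulate a small two-group cohort (hippocampal GluCEST 5.02 % vs
3.67 %), run the corrected pipeline, and compare groups:

```r
library(glucest)

co  <- generate_cohort(n_per_group = 4, shape = c(32, 32),
                       noise_sd = 0.01, seed = 7)
res <- run_pipeline(co)
res$tests$glucest_bilateral
#> <group_comparison> independent t-test (pooled variance)
#>    group n     mean        sd
#>  control 4 5.267017 0.7893116
#>      fst 4 2.893597 0.3732919
#> t = 5.4366, df = 6, p = 0.001608 (significant at 0.05)
```

Each row of `res$table` carries per-animal left, right and bilateral
hippocampal GluCEST means; recovered bilateral values track each
animal's generator target (drawn from the group mean ± between-animal
SD) to within the correction-chain tolerance:

```r
head(res$table[, c("id", "group", "glucest_left", "glucest_right",
                   "glucest_bilateral")], 3)
#>           id   group glucest_left glucest_right glucest_bilateral
#> 1 control_01 control     6.280111      6.286751          6.283431
#> 2 control_02 control     4.694850      4.342550          4.518700
#> 3 control_03 control     4.635251      4.937831          4.786541
```

(The group means differ from 5.02/3.67 here only through the n = 4
between-animal draw; at n = 12 the cohort means recover the targets
within two standard errors.) The underlying calibration is explicit:

```r
calibrate_contrast(5.02)   # pool fraction giving 5.02 % at 3.6 uT
#> [1] 0.0002149
```

See `vignettes/glucest-methods.Rmd` for the model, parameter defaults,
and numerical choices.

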