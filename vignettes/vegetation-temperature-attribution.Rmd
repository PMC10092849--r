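---
title: "Attributing vegetation effects on land surface temperature: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing vegetation effects on land surface temperature: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegtherm)
```

## The problem and the estimation strategy

Whether more vegetation cools or warms the land surface depends on the
balance of two pathways. Transpiring, aerodynamically rough canopies
dissipate absorbed energy efficiently as latent and sensible heat — a
cooling pathway — while darker canopies absorb more shortwave
radiation — a warming pathway. In water-limited drylands the cooling
pathway weakens (little water to transpire) while the albedo pathway is
strong, so the net sign of the vegetation feedback is an empirical
question with real consequences for how greening or aridification will
feed back on surface climate.

`vegtherm` estimates this net effect from gridded, co-registered
satellite-style fields, in three stages.

**Stage 1 — the response variable.** The diurnal statistic is the daily
median of 15-minute finite-difference LST rates over the 07:00–11:00
local-solar window, d(LST)/dt in K/h. During that window LST rises
nearly linearly, so the median rate integrates the surface energy
balance while being far less sensitive to cloud gaps and to the exact
timing of the daily peak than morning/afternoon snapshot differences.
Consecutive *valid* samples are differenced; a QC gap may be spanned by
a single longer increment.

**Stage 2 — conditioning.** Annual-mean rates are regressed on
annual-mean fraction of vegetation cover (FVC) *within bins* of pixels
whose long-term soil moisture agrees to ±0.0025 m³ m⁻³ and whose
long-term downwelling shortwave radiation agrees to ±1.25 W m⁻². Within
a bin, water and energy availability are controlled, so the across-pixel
FVC slope β_FVC is read as the effect vegetation differences would have
in time at a fixed location (space-for-time substitution). Significant
negative slopes are classified as cooling, significant positive slopes
as warming, insignificant slopes as neutral; the significance level is
0.05, two-sided, with no multiple-testing correction across bins
(mirroring per-bin significance usage; see Limitations).

**Stage 3 — mechanisms and accounting.** Energy-dissipation efficiency
β_Eff is the negated slope of rate versus concurrent LST, scaled by the
unitless normalization 32.5; albedo sensitivity β_α,FVC repeats the
binned regression with albedo as the response; and the tropical
interannual stage fits annual LST on annual NDVI with precipitation and
radiation controls per pixel, converts the NDVI coefficient to a ΔLST
per 1% relative greening, and quantifies how much drylands reduce the
net cooling of a uniformly greening domain.

## Tunable parameters

All pipeline parameters live in `analysis_config()`:

| parameter | default | units | why |
|---|---|---|---|
| `theta_half_width` | 0.0025 | m³ m⁻³ | bin tolerance for soil moisture: tight enough that members share water availability |
| `rs_half_width` | 1.25 | W m⁻² | bin tolerance for shortwave radiation |
| `dryland_threshold` | 500 | mm yr⁻¹ | the standard dryland rainfall line; strict `<`, so a pixel at the threshold is humid |
| `dryland_sensitivity` | 200 | mm yr⁻¹ | ±band for threshold sensitivity checks |
| `alpha_level` | 0.05 | – | two-sided significance for classification, CIs, trend screening |
| `fvc_report_step` | 0.1 | FVC | effects are reported per 0.1 absolute FVC increase |
| `morning_window` | [7, 11) | h, local solar | the near-linear rising limb of the diurnal cycle |
| `afternoon_window` | [12.5, 14.5] | h | afternoon-mean LST robustness variant |
| `dtr_times` | 13:30, 06:00 | h | assumed daily maximum and minimum for DTR |
| `min_pixels_per_regressor` | 10 | pixels | bins must supply 10 pixels per fitted coefficient (20 for the two-parameter fit, 40 for the four-parameter seasonal fit) to stabilise p-values |
| `min_valid_days` | 30 | days | minimum valid days behind an annual-mean rate (capped at the record length for short records) |
| `max_gap_hours` | 2 | h | longest QC gap one increment may span; bounds the attenuation a long-span increment could introduce |
| `bootstrap_reps` | 1000 | – | percentile-bootstrap resamples for group contrasts |

## What the synthetic generator emulates

`generate_scene()` produces the full input bundle on an `nx × ny`
lattice whose x-axis is an aridity gradient. Its defaults are the study
conditions under which the recovery tests run:

* **Aridity gradient.** Annual precipitation spans 100–1500 mm yr⁻¹,
  placing 28.6% of pixels below the 500 mm dryland line. Soil moisture
  rises and shortwave radiation falls smoothly (and deterministically)
  with rainfall, so conditioning bins form along the gradient.
* **Planted FVC effect.** β_FVC runs from +1 K h⁻¹ per unit FVC at the
  arid end, through an *exactly zero* neutral band, down to −5 K h⁻¹
  per unit FVC in humid terrain. The flat zero band gives the truth
  classification an honest neutral class; the transitions are smooth so
  borderline significance behaves realistically.
* **Diurnal shape.** Days are piecewise linear: flat before 06:00, a
  linear ramp of slope `r0(θ, R_S) + β_FVC · FVC` until 12:00, a
  plateau to 14:30, then linear decay. A piecewise-linear day (rather
  than a sinusoid) gives the morning-median rate an exact analytic
  truth, makes DTR = 6 h × slope, and so lets the rate statistics be
  tested to machine precision. `r0` is affine with coefficients shared
  by all pixels, so bins share baselines — exactly the assumption the
  conditional regression relies on.
* **Within-bin regressor variance.** FVC carries a deterministic
  within-column spread (±0.1) plus Gaussian noise; the deterministic
  part survives in noise-free mode so the regression never degenerates.
* **Seasonality.** Day-level FVC, θ, R_S and VPD follow one sine cycle
  with relative amplitudes 0.3, 0.25, −0.19 and −0.094 (θ in phase with
  vegetation; radiation and VPD out of phase). Under the FVC-median
  season split this yields a dryland low-vegetation season that is
  roughly 16% drier in soil moisture, 12% sunnier and 6% higher in VPD
  than the annual mean — the seasonal contrast regime of interest.
  Pixel-specific amplitude jitter (±20%) gives the seasonal controlled
  regression within-bin variance in its controls.
* **Albedo.** α = a₀(aridity) + β_α,FVC · FVC + noise with planted
  slopes −0.25 per unit FVC in drylands and −0.125 in humid pixels: a
  0.1 FVC increase darkens a dryland by 0.025, and drylands are exactly
  twice as albedo-sensitive as humid terrain.
* **Annual panels.** 19-year NDVI/LST/P/R_S series with planted
  coefficients; β_NDVI is sized as −5/mean(NDVI) in drylands and
  −10/mean(NDVI) elsewhere, so the planted ΔLST per 1% greening is
  −0.05 K and −0.10 K respectively and the dryland/humid sensitivity
  ratio is exactly 0.5.
* **Clouds.** Each 15-min sample is dropped independently with
  `cloud_gap_prob` (default 0.15).
* **Relaxation mode.** `relaxation_cube()` generates
  LST(t) = LST_eq − (LST_eq − LST₀)·e^(−kt), for which the rate-vs-LST
  slope has the closed form −(2/Δ)·tanh(kΔ/2); this is the oracle for
  the dissipation fit and its 32.5 normalization.

What it deliberately does **not** emulate: radiative-transfer realism,
spatially correlated cloud fields, orbital sampling, retrieval error
structure, NDVI saturation in dense forest, or topographic/edaphic
confounding. Noise is Gaussian and independent across pixels, days and
samples. Passing recovery tests therefore demonstrates that the
*estimators* are correct and calibrated under the model they assume —
not that real-scene confounders are absent.

## Numerical choices

* **Midpoint LST for the dissipation regression.** Each increment is
  paired with the mean of its two endpoint LSTs. On exponential
  relaxation this leaves a bias of order (kΔ)²/12 (the tanh
  correction, <0.01% at k = 0.1 h⁻¹), versus order kΔ/2 for a
  left-endpoint convention.
* **Gap-spanning cap.** Increments may span up to 2 h of QC gaps within
  the window; longer gaps produce no increment rather than a heavily
  attenuated slope estimate.
* **Window conventions.** The morning window is half-open
  [07:00, 11:00), making sample adjacency unambiguous at the
  boundaries; the afternoon window is closed.
* **Bin tiling.** Bins tile the (θ, R_S) plane anchored at zero with
  widths twice the half-tolerances (0.005 × 2.5). Tiling (not sliding
  windows) makes membership deterministic and disjoint; every member is
  within the stated tolerance of its bin centre.
* **Tie rules.** A day whose FVC equals the pixel's median joins the
  high-vegetation half; a pixel at exactly the dryland threshold is
  humid. Both follow from the strict inequalities in the definitions.
* **Missingness.** A day with fewer than two valid morning samples has
  no rate; an annual mean requires `min_valid_days` valid days; a
  constant-FVC pixel is excluded from seasonal analysis; a degenerate
  or undersized bin is flagged and not fitted but its pixels remain
  in the accounting as unclassified.
* **Degenerate fits.** Zero regressor variance, insufficient LST range
  (≤1 K) or fewer than 10 increments in the dissipation fit, and
  rank-deficient interannual fits all return missing values with
  reasons, never silent numbers.
* **Bootstrap.** Percentile bootstrap, 1000 reps, resampling at pixel
  level within groups; a contrast is significant when the 95% CI
  excludes zero. This matches bootstrap-of-bin-values reporting without
  assuming normality.
* **Detrending.** Linear trends are removed from annual LST and NDVI
  only when the two-sided trend p-value is below 0.05, and the
  operation is idempotent; P and R_S are never detrended.
* **Reduction accounting.** With two-valued ΔLST maps the reduction
  obeys reduction = 100·f·(1 − r) for dryland fraction f and
  dryland/humid sensitivity ratio r; the implementation is tested
  against this closed form on randomized (f, r).

## Design decisions that were genuinely open

* **"Concurrent LST" for the dissipation slope** could mean the left
  endpoint or the midpoint of an increment; the midpoint was chosen for
  its second-order bias (see above), and the choice is documented here
  rather than configurable, since the tanh correction assumes it.
* **Dissipation increments use the full diurnal cycle**, not only the
  morning window — the efficiency is a property of the whole
  relaxation, and restricting to the near-linear morning limb would
  leave almost no LST-range leverage.
* **Bins tile rather than slide.** A ± tolerance reads naturally as
  either; tiling gives each pixel exactly one bin and reproducible fit
  tables.
* **Area fractions are pixel counts** (the synthetic lattice is an
  equal-area abstraction); optional weights are accepted.
* **The t-test compares "with vs without drylands included"** (the
  all-pixels distribution against the humid-only distribution), with an
  independent dryland-vs-humid variant available — the overlapping form
  is conservative, the independent form is the one whose type-I error
  calibrates to 5%.
* **The 1% greening step is relative** (1% of each pixel's own mean
  NDVI), not an absolute 0.01 NDVI step.
* **Interface shape.** The pipeline is exposed as composable module
  functions returning classed S3 objects with `print`/`coef`/`confint`
  methods, plus four `assess_*()` chains; there is no shell entry
  point, because the intended use is scripted analysis. Scene I/O is a
  plain-text bundle (CSV tables + JSON metadata with explicit units)
  with a strict read-back contract that names any missing variable.

## Problem sizes

The recovery tests run on 60×60-pixel scenes with 40 days of 15-minute
sampling (the binned-regression and classification checks, 20 and 3
seeds respectively), 20×25-pixel field-only scenes for the albedo
contrast (20 seeds), a 500-pixel 19-year panel for the interannual
coverage check, and 1000-replicate null simulations for significance
calibration. These sizes give every check enough bins, pixels or
replicates for its stated bound while keeping a full run in the
low minutes on one CPU.

## Limitations

* Space-for-time substitution is an interpretive label: the conditional
  regression controls water and energy availability but cannot rule out
  other spatially structured confounders (soil type, topography,
  land-use history) on real scenes.
* Per-bin significance is used without multiple-testing correction
  across bins, mirroring standard per-bin usage; area fractions of
  "significant" classes inherit that choice.
* The generator's independence assumptions (no spatial noise
  correlation, independent cloud gaps) make recovery easier than on
  real retrievals with correlated error structure.
* The DTR-based interannual variant assumes 13:30/06:00 are the daily
  extremes; on real scenes peak timing drifts.
* NDVI is treated as linear in FVC; in dense forest NDVI saturates and
  the interannual sensitivity is attenuated.
```{r example, eval = FALSE}
# A minimal end-to-end run:
scene <- generate_scene(scene_config(nx = 30, ny = 30, n_days = 40, seed = 7))
cfg <- analysis_config()
a1 <- assess_fvc_effect(scene, cfg)     # binned FVC effects + classes
ss <- assess_seasonal(scene, cfg, a1)   # seasonal controlled regressions
me <- assess_mechanisms(scene, cfg)     # dissipation + albedo contrasts
a3 <- assess_tropics(scene, cfg)        # interannual Delta-LST accounting
```
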