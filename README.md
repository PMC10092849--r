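# vegtherm

Attribution of the net warming or cooling effect of vegetation cover on
land surface temperature (LST) from geostationary-style 15-minute LST
records, for land-surface biophysics and remote-sensing ecology work on
vegetated drylands.

Vegetation affects the surface energy balance through two competing
pathways: it usually cools by dissipating absorbed energy as turbulent
(latent and sensible) heat, and it warms by lowering surface albedo and
so increasing shortwave absorption. `vegtherm` implements an
observation-style pipeline that isolates the net effect along an aridity
gradient, diagnoses the mechanisms, and accounts for what drylands do to
the net cooling of a greening landscape — together with a synthetic
satellite-scene generator with planted parameters, so every stage is
testable by parameter recovery without any satellite downloads.

## The statistics at the core

**Morning warming rate.** From 15-min LST samples, d(LST)/dt is the daily
median of finite-difference rates over the 07:00–11:00 local-solar
window (K/h), computed over time-adjacent valid samples (QC gaps may be
spanned, up to 2 h). The rate integrates the diurnal cycle while being
robust to cloud gaps; on piecewise-linear diurnal cycles it relates to
the diurnal temperature range as DTR = 6 h × rate.

**Space-for-time conditional regression.** Pixels with near-identical
long-term soil moisture (±0.0025 m³ m⁻³) and shortwave radiation
(±1.25 W m⁻²) are binned; within each bin,

    E[d(LST)/dt] = β₀ + β_FVC · E[FVC] + ε

so that across-pixel differences in fraction of vegetation cover (FVC)
stand in for temporal vegetation change under controlled water and
energy availability. Significantly negative β_FVC (p < 0.05) is a
cooling effect, significantly positive a warming effect, anything else
neutral; effects are reported per 0.1 absolute FVC increase. A seasonal
variant adds seasonal-mean θ and R_S as controls, and an interannual DTR
variant checks that the spatial relationships also hold in time.

**Mechanisms.** Energy-dissipation efficiency is the negated slope of
d(LST)/dt versus concurrent LST, normalized to be unitless by the
factor 32.5 (force-restore scaling):

    d(LST)/dt = β₀ + (−β_Eff) · LST + ε

Albedo sensitivity repeats the binned regression with surface albedo as
the response (E[α] = β₀ + β_α,FVC·E[FVC] + ε). Dryland-vs-humid
contrasts (500 mm yr⁻¹ rainfall threshold, ±200 mm sensitivity) carry
percentile-bootstrap 95% confidence intervals.

**Tropical interannual attribution.** Per pixel, 19-year annual panels
are fit by

    E[LST] = β₀ + β_NDVI·E[NDVI] + β_P·E[P] + β_RS·E[R_S] + ε

after removing statistically significant linear trends from LST and
NDVI. ΔLST = β_NDVI × 1% of mean annual NDVI is the LST change per 1%
relative greening, and the dryland reduction of net cooling compares the
ΔLST distribution with and without drylands included:
reduction = 100 × (mean_humid − mean_all) / mean_humid (and the median
analogue), with a Welch t-test between the two distributions.

## Worked example

```r
library(vegtherm)
scene <- generate_scene(scene_config(nx = 30, ny = 30, n_days = 40, seed = 7))
cfg <- analysis_config()

a1 <- assess_fvc_effect(scene, cfg)
print(a1)
#> <vt_assessment1> net FVC effect on d(LST)/dt
#>   30 bins (30 fitted); classified pixels: 890
#>   cooling 67.4% | neutral 10.1% | warming 22.5% of classified area

a3 <- assess_tropics(scene, cfg, mask_mode = "fvc_zero")
print(a3$reduction)
#> <vt_reduction> Delta-LST mean: all -0.08445 K, humid -0.09857 K, dryland -0.05023 K
#>   dryland reduction of net cooling: 14.3% (mean), 5.9% (median); drylands 29.2% of area; t-test p = 5.15e-41
```

The scene plants an FVC effect running from +1 K/h per unit FVC at the
arid end through an exactly neutral band to −5 K/h per unit FVC in humid
terrain, so most classified area cools, with warming confined to the dry
margin. The tropical panel plants greening sensitivities of −0.05 K
(drylands) and −0.10 K (humid) per 1% NDVI increase; with ~29% dryland
area the mean net cooling across the domain is reduced by ~14% relative
to the humid-only mean — exactly the accounting identity
reduction = 100 · f · (1 − r) for dryland fraction f and
dryland/humid sensitivity ratio r.

Mechanism diagnostics run the same way:

```r
mech <- assess_mechanisms(scene, cfg)   # dissipation efficiency + albedo bins
ss   <- assess_seasonal(scene, cfg)     # seasonal controlled regressions
```

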