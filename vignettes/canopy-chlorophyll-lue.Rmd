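---
title: "Estimating light use efficiency and midday GPP from canopy chlorophyll"
author: "canopylue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating light use efficiency and midday GPP from canopy chlorophyll}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopylue)
```

## The model

Light-use-efficiency (LUE) models estimate gross primary productivity as
`GPP = PAR × fAPAR × LUE`. Because LUE tracks canopy chlorophyll — the
machinery that actually absorbs and uses light — this package factors it
as `LUE = α × CCC`, giving the working model

```
GPP = PAR × fAPAR_green × α × CCC
```

with `PAR` the incident photosynthetically active radiation
(μmol photons m⁻² s⁻¹), `fAPAR_green` the fraction absorbed by green
canopy elements, `CCC` the canopy chlorophyll content (g m⁻² ground
area), and `α` a per-chlorophyll light-use coefficient
(μmol CO₂ · (μmol photons)⁻¹ · (g Chl m⁻²)⁻¹). `α` is not assumed; it is
calibrated per CCC indicator by a through-origin least-squares slope
(`calibrate_alpha()`), because the model has no intercept and different
spectral indicators imply different effective radiation-use per gram of
inferred chlorophyll.

The chain has three measurement legs:

* **CCC from leaf optics:** SPAD readings of the standard plants are
  averaged per campaign and converted by `Chl = 10^(M^0.265)` (μmol m⁻²),
  `LCC = Chl × 0.89701` (mg m⁻²), `CCC = LAI × LCC × 10⁻³` (g m⁻²). The
  printed form of the SPAD calibration is typographically ambiguous
  between `10^(M^0.265)` and `10^(0.265·M)`; the power reading is used
  because the product reading produces impossible chlorophyll contents
  (≈10¹⁰ μmol m⁻² at M = 40). The product reading remains available as
  `spad_to_chl(form = "product")` for fidelity experiments.
* **CCC from spectra:** chlorophyll-related vegetation indices
  (`compute_index()`), the red edge position (`compute_rep()`), and
  optimal two-band indices found by exhaustive search
  (`band_search()`), each calibrated against the SPAD-derived CCC with a
  linear or exponential regression (`fit_ccc_estimator()`). Exponential
  forms are fitted by log-linearisation: deterministic, fast enough for
  ~3 million pair fits, and matching the saturating index–CCC shapes; the
  reported R² is that of the linearised model (on which scale a published
  exponential R² is computed is generally unstated, so the choice is made
  explicit here).
* **GPP from the tower:** half-hourly NEE (positive = emission) is
  partitioned with a Lloyd–Taylor respiration fitted to nighttime NEE in
  91-day moving windows, then `GPP = −NEE + Reco` in the daytime and
  GPP = 0 at night; midday GPP is the 11–14 h mean.

## Numerical and convention choices

* **Temperatures** are Kelvin throughout, with `T_0 = 273.15 K` and
  `T_ref = 283.15 K`, so `T − T_0` reproduces Celsius soil temperature.
  In this parameterisation the temperature-sensitivity parameter `E0`
  carries units of K (a value near 14 gives Q10 ≈ 2 between 10 and
  20 °C), despite often being labelled an activation energy. Frozen soil
  (`T ≤ T_0`) is outside the model domain and yields `NA`.
* **Nighttime** is `PAR < 10 μmol m⁻² s⁻¹` (configurable). The generator
  emits PAR exactly 0 at night, so in tests any threshold below the first
  daylight value behaves identically.
* **Respiration windows** are centred on each day, advanced daily, and
  truncated at the season edges; days with fewer than 20 nighttime
  records inherit the nearest valid day's parameters and are flagged.
  Fits use Levenberg–Marquardt least squares with deterministic
  initialisation (`R_ref` = mean nighttime NEE, `E0` = 14) and tight
  tolerances so noise-free recovery is exact to solver precision.
* **REP** is the argmax of the raw central first difference on the 1-nm
  grid over 680–750 nm — no smoothing, ties broken toward the shorter
  wavelength, undefined (NA) when the maximum slope is ≤ 1e-5 nm⁻¹, which
  flags flat and vegetationless spectra instead of fabricating a red
  edge. Undefined index values generally propagate as `NA`, never as
  errors, so season tables keep their shape.
* **Band search** covers integer wavelengths 400–1300 nm (configurable
  step). Regression response is CCC with the index as predictor. A pair
  is dropped when any sample's index is undefined or the index is
  constant, keeping `n` identical across the map. The NDVI map is
  mirrored from its upper triangle because an NDVI band swap is a pure
  sign flip absorbed by the regression slope; WDRVI does *not* share this
  symmetry at weights other than 1 (the swap is not a sign flip), so
  WDRVI, RVI and EVI2 maps are computed in full. The WDRVI weight
  defaults to 0.2, within the 0.1–0.2 range its source recommends; it is
  named `wdrvi_weight` to avoid any collision with the LUE coefficient α.
* **EVI's blue band** is the MODIS band-3 range 459–479 nm (the broadband
  convention used for red and NIR), configurable.
* **fAPAR_green** is clamped to [0, 1]: the calibration line exceeds 1
  above NDVI ≈ 0.98 and is negative below 0.171.
* **Validation** regresses measured on estimated midday GPP with a free
  intercept, while α calibration is through the origin; RMSE is reported
  on the 1:1 comparison. GPP is converted to μmol CO₂ m⁻² s⁻¹ with
  44.01 g mol⁻¹ before calibration.

## What the synthetic generator emulates

`season_config()` encodes the study conditions: one rain-fed maize
season (May–September), nine biweekly campaigns with five standard
plants, and half-hourly fluxes. CCC and LAI follow double-logistic
(rise × senescence) curves peaking at 2.5 g m⁻² and 4.5 around DOY 210 —
a single-peak trajectory with a late-July/early-August maximum and
realistic leaf chlorophyll (≈300–560 mg m⁻², SPAD ≈ 34–48). LAI declines
more slowly than CCC after the peak (leaves yellow before they fall).
Default noise levels are chosen from instrument characteristics, not
tuned: 1 SPAD unit repeatability, 0.002 reflectance noise (field
spectrometer class), 10 % relative plus 0.01 mg m⁻² s⁻¹ additive NEE
error (typical eddy-covariance random uncertainty), log-normal cloud
modulation of PAR (sd 0.15). Planted respiration (`R_ref` = 0.08
mg CO₂ m⁻² s⁻¹ at 10 °C, `E0` = 14 K) and `α` = 0.008 give midsummer
midday GPP near 40 μmol m⁻² s⁻¹, in the range of productive maize.

Spectra are built as a gap-fraction mixture of a near-flat soil line and
a vegetation endmember with a chlorophyll-deepened red trough, a red-edge
sigmoid whose inflection saturates as `700 + 40·ccc/(ccc+1)` nm, an
LAI-driven NIR plateau, and water dips near 970 and 1200 nm. On top of
that shape the generator *plants* three exact index–CCC relations
(`planted_relations()`): broadband NDVI follows
`CCC = 0.0067·e^(6.6986·NDVI)` (coefficients matching a published maize
calibration), and two EVI2 pairs, [1214, 1259] and [820, 1248], follow
exact linear relations. The second pair sits on the NIR plateau rather
than the red edge: planting an exact relation at a wavelength inside the
680–750 nm window would deform the red-edge shape that the REP indicator
depends on. These plantings make the zero-noise pipeline exactly
invertible for the NDVI and EVI2 estimators, which is what turns
end-to-end runs into sharp recovery tests.

The REP chain is deliberately *not* exactly invertible: REP lives on the
integer-nm grid, so even noise-free REP carries ±0.5 nm quantisation.
Its zero-noise validation R² is ≈ 0.98, not 1 — an inherent property of
a 1-nm argmax red edge, worth knowing before using REP calibrations on
sparse canopies, where the red-edge slope is weak and REP becomes noisy
or undefined.

For band-search recovery experiments, `plant_ccc_from_pair()` builds CCC
labels as an exponential function of the *measured* EVI2 at one
designated pair (plus 0.2 % label noise), in spectra generated with
`planting = NULL`. Both choices matter: labels must inherit the pair's
own channel noise for the pair to be uniquely informative among ~33,000
candidates at n = 9, and the generator's other planted relations would
otherwise tie with the designated pair exactly. The recovery pair
[1215, 1260] lies on the 5-nm coarse grid used for replicated runs. Top
pairs are compared unordered, since the full-square R² map treats
(λ₁, λ₂) and (λ₂, λ₁) as the same combination for the symmetric story.

What passing these tests does *not* show: the generator is an explicit
statistical stand-in, not a radiative-transfer model (no PROSAIL), so
recovery results say nothing about atmospheric effects, canopy
structure/soil-background coupling, view geometry, or gap-filled flux
records (synthetic series are gap-free; u*-filtering, WPL and despiking
are upstream concerns out of scope here). Real-data performance of any
specific band pair must be established on real data.

## Problem sizes and determinism

Default experiments use the nine-campaign season (9 spectra of 951
bands), a 153-day half-hourly flux series (7,344 records, ~25 nighttime
half-hours per day), the full 901-wavelength search (≈405,450 unordered
pairs × 4 forms × 2 regressions, a few seconds via accumulated
outer-product moments), and 20-replicate seeded ladders for noise
studies. Every stochastic path flows from one master seed
(`season_config(seed = )`); campaign dates and truth trajectories are
seed-independent, so changing the seed changes only noise realisations.

## Known limitations

* The SPAD molar-mass constant 897.01 g mol⁻¹ is applied as printed in
  its source without asking whether it represents chlorophyll-a alone or
  an a+b mixture.
* Exponential fits require strictly positive CCC; bare-soil campaigns
  must be excluded before calibration.
* The red-edge argmax is not sub-nm accurate by design (see above);
  derivative smoothing or parabolic refinement would change the REP
  contract and is intentionally not applied.
* No multiple-testing correction is applied over the band-pair grid, and
  the band selection is not cross-validated; ranked pairs should be read
  as descriptive optimisation output, not hypothesis tests.
```{r example}
res <- run_pipeline(season_config(seed = 42))
res$validations[, c("estimator", "predictor", "form", "alpha", "r2", "rmse")]
```
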