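# canopylue

Estimation of maize-canopy light use efficiency (LUE) and midday gross
primary productivity (GPP) from *in situ* hyperspectral reflectance and
eddy-covariance CO₂ flux measurements.

The package is aimed at crop ecophysiologists and flux-tower scientists who
want to link field spectrometry to tower GPP. It implements the full chain:

1. **Canopy chlorophyll content (CCC).** SPAD-502 readings and leaf area
   index are converted through
   `Chl (μmol m⁻²) = 10^(M^0.265)`,
   `LCC (mg m⁻²) = Chl × 897.01 × 10⁻³`,
   `CCC (g m⁻²) = LAI × LCC × 10⁻³`.
2. **Spectral indicators.** Eleven common chlorophyll-related vegetation
   indices (NDVI, EVI, RVI, red-edge NDVI, PRI, MCARI₇₁₀, CI_green,
   CI_red-edge, MTCI, CCI, WDRVI) with MODIS-style broadband means, plus the
   red edge position (REP) as the wavelength of maximum first-derivative
   reflectance in 680–750 nm.
3. **Two-band index optimisation.** Exhaustive evaluation of NDVI, RVI,
   WDRVI and EVI2 over all combinations of two separate wavelengths in
   400–1300 nm against CCC, under linear and exponential regressions,
   producing R² maps and ranked optimal band pairs.
4. **Flux partitioning.** `NEE = w′c′̄` (positive = emission); nighttime
   NEE fitted to the Lloyd–Taylor temperature response
   `Reco = R_ref · exp(E0 · (1/(T_ref − T_0) − 1/(T − T_0)))`
   in 91-day moving windows; daytime `GPP = −NEE + Reco` (GPP = 0 at
   night); midday GPP averaged over 11–14 h.
5. **LUE model.** `GPP = PAR × fAPAR_green × α × CCC`, with
   `fAPAR_green = 1.235 × NDVI − 0.211` (clamped to [0, 1]) and the
   light-use coefficient α calibrated as a through-origin least-squares
   slope; estimated GPP is validated against tower midday GPP.

Because no field data are distributed with this problem, the package ships
a first-class synthetic-season generator (`season_config()`,
`simulate_season()`) that plants a known truth — single-peak CCC/LAI
trajectories, spectra with an exact, recoverable index–CCC structure, and
half-hourly fluxes built from known `R_ref`, `E0` and α — so every stage
can be tested against what was planted.

## Worked example

```r
library(canopylue)

cfg <- season_config(seed = 42)   # realistic field-noise defaults
res <- run_pipeline(cfg)
res
#> <lue_pipeline> validation of estimated vs measured midday GPP:
#>   estimator       predictor        form    alpha r2_ccc     r2   rmse
#>        ndvi            NDVI exponential 0.008184 0.9995 0.9993 0.3574
#>         rep             REP exponential 0.007777 0.9671 0.9810 1.7404
#>  evi2_pair1 EVI2[1214,1259]      linear 0.008210 0.9855 0.9944 0.9644
#>  evi2_pair2  EVI2[820,1248]      linear 0.008155 0.9955 0.9970 0.6648
```

Each row is one CCC estimator: `r2_ccc` is the fit of the estimator
against the SPAD-derived CCC on the nine campaign days, `alpha` the
through-origin light-use coefficient calibrated for that estimator
(planted truth 0.008), and `slope`/`r2`/`rmse` the regression of
tower-measured on model-estimated midday GPP (μmol CO₂ m⁻² s⁻¹). With all
noise switched off (`zero_noise(cfg)`) the NDVI and EVI2-pair chains are
exact (R² = 1 and α recovered to ~1e-16); REP is quantised to the 1-nm
grid and lands near R² ≈ 0.98.

The exhaustive search itself:

```r
sim <- simulate_season(zero_noise(season_config()))
maps <- band_search(sim$spectra, sim$samples$ccc)   # 901 × 901 × 8 maps, ~5 s
best_pairs(maps$evi2_linear, 3)
#> # A tibble: 3 x 5
#>   lambda1 lambda2    r2 form  regression
#> 1    1214    1259 1     evi2  linear
#> 2     820    1248 1     evi2  linear
#> 3    1215    1257 1.000 evi2  linear
```

The two planted EVI2 pairs top the map exactly (the third row is a
neighbour riding on the planted feature).

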