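# shadespec

Sunlit/shaded canopy component analysis for near-ground imaging
spectroscopy of crop canopies.

At millimetre ground resolution a rice canopy image is a mixture of four
spectrally distinct targets — sunlit leaves (SL), shaded leaves (SHL),
sunlit panicles (SP) and shaded panicles (SHP). Shading lowers
reflectance amplitude but *deepens* apparent absorption features, so the
two populations of leaf pixels respond differently to chlorophyll and
must be separated before canopy chemistry can be estimated reliably.
`shadespec` implements the whole chain for users working with
visible/NIR (400–900 nm) pushbroom imagery: radiometric calibration,
MNF denoising, vegetation masking, continuum removal, vegetation
indices, component classification, and the sunlit-versus-shaded
chlorophyll regression comparison. A labelled synthetic-scene generator
makes every stage testable without field data.

## Methods at a glance

* **Calibration**: `Ref = (DN − DN_noise) / (DN_panel − DN_noise) × Ref_panel`,
  per band, from dark-current and white-panel measurements.
* **Vegetation indices** (R_λ = reflectance at λ nm):
  * NDVI = (R800 − R670) / (R800 + R670)
  * TCARI = 3[(R700 − R670) − 0.2 (R700 − R550)(R700 / R670)]
  * PRI = (R531 − R570) / (R531 + R570)
  * CI_red-edge = R800 / R720 − 1
  * EVI = 2.5 (R800 − R670) / (R800 + 6 R670 − 7.5 R470 + 1), masking
    non-vegetation at EVI ≤ 0.45.
* **Continuum removal**: division by the upper convex hull over the blue
  (400–550 nm) and red (550–750 nm) windows; band depth = 1 − min.
* **Spectral matching**: SAM (angle between spectra) and SID
  (symmetrised relative entropy of sum-normalised spectra) against class
  mean spectra.
* **Decision tree**: PRI splits leaves from panicles (leaves higher),
  then TCARI splits sunlit from shaded (sunlit higher); each threshold is
  the midpoint of the two group means, stage-averaged over the season.
  Evaluated by stratified ten-fold cross-validation with per-fold
  threshold re-derivation.
* **Chlorophyll bookkeeping**: LCC (µg/cm²) = 1.4498 × SPAD − 22.014;
  CCC (g/m²) = LCC × LAI × 0.01; Spearman R², paired t-tests, and
  linear/exponential fits of z-scored indices against CCC for SL, SHL
  and combined pixels.

## Worked example

Generate a four-plot synthetic season, build a region-of-interest
spectral library from the truth labels, derive decision-tree thresholds,
and cross-validate:

```r
library(shadespec)

season <- generate_season(SceneConfig(rows = 40, cols = 40),
                          n_plots = 4, seed = 1)
lib <- roi_library(season$scenes, n_per_class = 20, seed = 1)
vi  <- library_vi_table(lib)

derive_thresholds(vi)
#> Decision-tree thresholds:
#>   PRI leaf/panicle split: 0.0702
#>   TCARI SL/SHL split: 0.1216
#>   TCARI SP/SHP split: 0.0699

cv <- cross_validate(vi, folds = 10, seed = 1)
cv$confusion
#>      predicted
#> truth  SL SHL  SP SHP
#>   SL  465   8   7   0
#>   SHL   0 480   0   0
#>   SP    0   0 417  63
#>   SHP   0   0  21 459
sprintf("overall accuracy: %.1f%%", 100 * cv$accuracy)
#> [1] "overall accuracy: 94.8%"
```

The thresholds say that leaf pixels have PRI above ~0.07 while panicle
pixels sit near zero, and that within each organ the sunlit population
has roughly twice the TCARI of its shaded counterpart — the amplitude
signature of direct illumination. Classify a full heading-stage scene
and compare leaf populations:

```r
th <- derive_thresholds(vi)
sc <- season$scenes[[5]]            # plot 1, heading
map <- classify_image(sc$cube, th, evi_mask(sc$cube))
map
#> LabelMap: 40 x 40 pixels
#> NONVEG    SHL    SHP     SL     SP
#>    327    696    155    291    131
sunlit_shaded_ratio(map)
#> [1] 0.42

sv <- season_class_vi(season)
spearman_r2(sv$ccc[sv$class == "SL"],  sv$tcari[sv$class == "SL"])$r2_spearman
#> [1] 0.56
spearman_r2(sv$ccc[sv$class == "SHL"], sv$tcari[sv$class == "SHL"])$r2_spearman
#> [1] 0.79
```

Shaded leaf pixels outnumber sunlit ones at heading (ratio 0.42), and
TCARI from shaded leaves tracks canopy chlorophyll much more tightly
(R² 0.79 vs 0.56) — the central reason to separate the two populations
before estimating canopy chemistry.

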