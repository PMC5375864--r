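---
title: "Separating sunlit and shaded canopy components in imaging spectroscopy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{shadespec methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shadespec)
```

## The problem

Near-ground imaging spectroscopy of crop canopies resolves individual
leaves and panicles at millimetre scale. At that resolution a canopy is
not one spectral target but at least four: sunlit leaves (SL), shaded
leaves (SHL), sunlit panicles (SP) and shaded panicles (SHP). Shading
changes a pixel's spectrum in two distinct ways — diffuse irradiance
lowers the overall amplitude, while multiple scattering within the canopy
deepens the *apparent* absorption features — and the two effects pull
vegetation indices in different directions. Pooling sunlit and shaded
pixels therefore biases chlorophyll estimation, and the shaded fraction,
far from being negligible, typically outnumbers the sunlit fraction once
the canopy closes.

`shadespec` implements the full analysis chain for this problem:

1. **Preprocessing** (`calibrate`, `mnf_denoise`, `subset_bands`,
   `evi_mask`): raw digital numbers to relative reflectance via
   dark-current and white-panel calibration, minimum-noise-fraction
   smoothing, restriction to the quiet 400–900 nm range, and an
   EVI > 0.45 vegetation mask.
2. **Spectral mathematics** (`continuum_remove`, `band_depth`,
   `class_mean_spectrum`): continuum removal by upper convex hull over the
   blue (400–550 nm, carotenoid) and red (550–750 nm, chlorophyll)
   windows.
3. **Vegetation indices** (`ndvi`, `tcari`, `pri`, `ci_red_edge`, `evi`):
   narrow-band indices with anchors resolved by nearest-band lookup.
4. **Classification** (`sam`, `sid`, `match_classify`,
   `derive_thresholds`, `classify_image`, `cross_validate`): spectral
   matching against class mean spectra, and a two-level decision tree —
   PRI separates leaves from panicles, then TCARI separates sunlit from
   shaded within each branch.
5. **Chlorophyll statistics** (`spad_to_lcc`, `canopy_chl`,
   `spearman_r2`, `compare_groups`): SPAD-meter conversion to leaf
   chlorophyll content (LCC), canopy chlorophyll content
   (CCC = LCC × LAI × 0.01, in g/m²), and the sunlit-versus-shaded
   regression comparison with z-score normalisation.
6. **Synthetic scenes** (`generate_scene`, `generate_season`): a labelled
   generator standing in for field imagery, described next.

## Why a synthetic generator, and what it encodes

No public imagery accompanies this kind of field study, so every stage is
exercised against synthetic scenes whose *structure* — not whose numeric
values — matches what the analysis assumes. The generator is first-class,
tested code; its defaults define the study conditions used throughout the
test suite and the acceptance script.

### The component reflectance model

Each class is a `ComponentModel`:

$$R(\lambda) \;=\; s \cdot P(\lambda)\cdot
\prod_i \Bigl(1 - d_i\, \beta\, e^{-(\lambda - c_i)^2 / 2 w_i^2}\Bigr)
\cdot \varepsilon(\lambda)$$

* $P(\lambda)$ is an absorption-free plateau: a visible baseline rising
  through a logistic red-edge ramp (centre 722 nm, width 9 nm) to a NIR
  plateau.
* Gaussian absorption features $(c_i, w_i, d_i)$ model pigment bands.
  Leaves carry a blue carotenoid+chlorophyll feature (460 nm), a
  green-yellow chlorophyll shoulder (580 nm) and the red chlorophyll
  feature (668 nm). Panicles, being roughly an order of magnitude poorer
  in pigments, carry two *narrow* blue features (450 and 492 nm) — which
  produce the tell-tale double minimum in blue-window continuum-removed
  spectra — plus a weak shoulder and a shallow red feature.
* Shading is two independent knobs: the amplitude factor $s \in (0,1]$
  (0.55 for shaded leaves, 0.65 for shaded panicles; 1 for sunlit) and
  the absorption boost $\beta \ge 1$ (1.15 leaves, 1.12 panicles) that
  deepens every feature. This reproduces both halves of the observed
  contrast: shaded pixels are darker *and* show deeper continuum-removed
  absorption.
* $\varepsilon$ is pixel noise with three components, all multiplicative
  and mean-one: a spectrally flat log-normal amplitude factor
  (SD 0.06 — pixel-to-pixel illumination and geometry), a smooth spectral
  tilt `1 + t(λ−450)/450` with SD(t) = 0.08 (leaf-angle and
  multiple-scattering variation, which mostly moves the NIR plateau), and
  iid per-band log-normal noise (SD 0.02 — sensor noise). Purely iid
  band noise would be both unrealistically harsh on narrow-band ratio
  indices (neighbouring bands decorrelate) and unrealistically kind to
  whole-spectrum matching; real within-class variance is dominated by
  spectrally smooth effects, which is what the amplitude and tilt terms
  provide.

Stage dependence: the leaf NIR plateau rises from early tillering (0.38)
to heading (0.54) and falls at filling, while the panicle plateau is
stage-constant (0.52). Chlorophyll-linked depths scale with leaf
chlorophyll as $\mathrm{rel}^{0.7}$ ($\mathrm{rel} = \mathrm{LCC}/42$);
the sublinear exponent reflects the saturation of deep absorptions.
Panicle depths use the much weaker coupling $1 + 0.3(\mathrm{rel}-1)$ —
panicle pigments simply do not track leaf nitrogen status closely, and
this is also what keeps the panicle TCARI range compact enough for a
single season-wide threshold.

### The season generator

`generate_season` emits, per plot and stage, a labelled scene and a plot
record. Leaf chlorophyll truth follows a rise–fall trajectory peaking at
heading with a local dip at jointing (stage means 38, 42, 39.5, 44, 47,
43 µg/cm²), nitrogen-rate offsets of −6 to +2.5 µg/cm², and SPAD readings
generated by the 3-leaves × 3-readings protocol so that the
SPAD → LCC → CCC chain is internally consistent by construction. LAI
peaks at booting (6.2 m²/m²), so CCC peaks at booting while LCC peaks at
heading; the resulting CCC span (~0.15–3.5 g/m²) is a plausible field
range, not a reproduction of any particular dataset.

Two asymmetries give shaded leaves the stronger index-to-chlorophyll
coupling that motivates the whole analysis: sunlit classes receive a
*scene-level* illumination jitter (log-normal, SD 0.04, independently on
amplitude and on depths) that shaded, diffusely lit classes do not. The
amplitude jitter directly perturbs TCARI (the one amplitude-sensitive
index) and the depth jitter perturbs all indices' coupling, so Spearman
R² comes out systematically higher for shaded leaves — an encoded
mechanism (sun-angle and sky-condition variation between acquisitions),
not a numeric fit to any reported table.

Class areal fractions are stage-dependent: at early tillering the canopy
is open (36% SL, 22% SHL, 33% background), afterwards shaded foliage
dominates (18% SL, 42% SHL). Consequently the classified sunlit/shaded
pixel ratio is well above 1 at early tillering and near 0.44 later — the
qualitative pattern reported for real paddy canopies.

### What the generator does *not* emulate

No radiative transfer (leaf biochemistry to reflectance is parametric,
not PROSAIL), no BRDF or row-structure geometry, no illumination-angle
modelling, no spectrally correlated sensor artefacts (smile, striping),
and no mixed pixels — every pixel is a pure class sample. Tests passing
on these scenes therefore demonstrate that the *pipeline logic* is
correct and that the qualitative patterns reported for real canopies are
recoverable when present; they do not certify performance on field
imagery.

## Numerical and design choices

* **Continuum removal**: the upper hull is computed by Andrew's monotone
  chain on the in-window points and evaluated by linear interpolation;
  windows are closed intervals; output is clamped at 1 against rounding.
  Division-by-zero hulls raise an error rather than returning infinities.
* **Band lookup**: anchors resolve to the nearest band within twice the
  median grid step by default; exact ties go to the lower wavelength.
  The resolved indices are recorded in every `VIResult` for audit.
* **EVI**: the formula's coefficients (2.5, 6, 7.5, +1) follow the
  standard published form with 800/670/470 nm anchors. The mask is a
  strict inequality: EVI exactly at the threshold is background.
* **MNF**: noise covariance from along-row first differences divided by
  √2 (the classic construction), regularised by adding 10⁻¹⁰ × mean
  diagonal when near-singular; forward-plus-inverse reconstruction keeps
  the output in reflectance space. The default component count keeps
  noise-whitened eigenvalues above 1. The shift-difference estimator
  assumes neighbouring pixels share signal, so callers should expect
  degraded behaviour on spatially white "images".
* **Calibration** is not clipped above 1 (specular pixels legitimately
  exceed the panel) but is floored at 0, since sensor noise can push a
  dark pixel below the dark reference and negative reflectance has no
  physical reading.
* **SID floor**: values ≤ 0 are floored at 10⁻⁶ before the probability
  normalisation, keeping the relative entropy defined on calibrated zeros
  with negligible distortion.
* **Continuum-removed matching space**: the blue-window and red-window
  segments are concatenated (the shared 550 nm point kept once).
* **Threshold derivation** averages within stage first, then across
  stages, so each stage carries equal weight over the season; pooled
  averaging is available as an option. Boundary equality in the tree goes
  to the leaf branch, then the sunlit branch — documented and tested.
* **Cross-validation** re-derives thresholds inside every training fold
  (the honest protocol: thresholds are part of the fitted model), with
  stratified per-class fold assignment.
* **Exponential fits** are nonlinear least squares initialised from the
  log-linear fit of ln y on x; if the optimiser fails the log-linear
  solution itself is returned (it is exact under log-normal noise). R² is
  always computed on the original scale. Z-scored predictors may be
  negative; only the response must be positive, so `compare_groups`
  shifts each z-scored index by the same constant (min + 1) in every
  group before the exponential fit.
* **Paired t-tests** pair class means by scene × stage.
* **Units**: LCC in µg/cm², LAI in m²/m², CCC in g/m² via the ×0.01
  conversion; SPAD → LCC is the linear meter calibration
  1.4498 × SPAD − 22.014.

## Problem sizes used by the tests and the acceptance script

The test suite exercises scenes of 10×10 to 50×50 pixels, seasons of 3–6
plots, libraries of ~2000 spectra, and 100-instance hull-oracle
comparisons; the acceptance script generates a 12-plot × 6-stage season
of 50×50-pixel scenes (a 5760-spectrum library) — sizes chosen so the
statistical assertions have comfortable margins while a full run stays in
the tens of seconds on one CPU.

## Known limitations

* Generator amplitudes are free parameters constrained only by the
  qualitative orderings the analysis needs; none of the numeric index
  values or R² magnitudes it produces should be read as predictions for
  field data.
* At early tillering the shaded-leaf class mean EVI (~0.41) sits below
  the 0.45 vegetation mask, so masked maps undercount shaded leaves at
  that stage. This mirrors the anomalously high sunlit/shaded ratio
  observed at open canopies, and is left as-is deliberately.
* `match_classify` applies season-pooled reference means by default; a
  per-stage option exists but the headline accuracies use the pooled
  protocol.
* The ENVI dialect is deliberately small: BSQ/BIL/BIP read, BSQ write,
  float32/uint16 samples, no georeferencing and no `.sli` binary
  libraries (spectral libraries persist as CSV for diffability).
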