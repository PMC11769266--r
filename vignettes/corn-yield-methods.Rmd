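---
title: "Methods: field-scale corn yield prediction from multispectral imagery, soil and terrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: field-scale corn yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyield)
```

## The problem

A combine-mounted yield monitor produces thousands of georeferenced grain
yield records per field. Drone-borne 5-band multispectral cameras (blue,
green, red, red-edge, NIR) resolve the canopy at centimeter scale across
the vegetative season, and public databases provide gridded soil
properties (sand/silt/clay, organic matter, bulk density, available water
capacity) and elevation. `canopyield` implements the complete chain that
connects these sources: it assigns each yield record its Thiessen-polygon
footprint, averages co-registered rasters over each footprint, derives a
large registry of spectral indices from the averaged reflectance, and
compares four regression methods — multiple linear regression (MLR),
random forest (RF), gradient boosting (GBR) and XGBoost (XGB) — at
predicting yield per growth stage, with and without the soil/terrain
predictors.

Because production yield-monitor and drone data are rarely
redistributable, the package ships a synthetic-field generator with known
ground truth; every claim the pipeline makes is validated against that
truth or against independent oracles in the test suite.

## Pipeline model and assumptions

**Bare-ground masking.** Early-stage imagery mixes canopy and soil
pixels. Pixels are classified by red-edge NDVI,
`NDVIre = (RE - R)/(RE + R)`, which is near zero for bare soil (flat red
edge) and high for green canopy. The threshold is either supplied
per flight or chosen automatically by Otsu's between-class-variance
maximization over a 256-bin histogram. Masked pixels become *nodata*,
never literal zero reflectance: a zero would silently poison the zonal
means that follow, whereas nodata pixels are simply excluded, which is
the evident intent of masking before averaging.

**Zonal features.** Each harvest point's footprint is its Voronoi
(Thiessen) cell clipped to the field boundary, computed exactly by
successive half-plane clipping with a 2x-max-radius neighbor cutoff
(exact for convex boundaries). Cells are filtered by area (default
0.5x-2x the nominal per-record area), by the isoperimetric roundness
`P^2/(4*pi*A)` (default max 3), and by boundary contact — irregular and
edge cells are unreliable footprints. The per-cell mean of every raster
uses the pixel-center containment rule, ignoring nodata; cells with no
valid pixel are flagged rather than dropped silently. Spectral indices
are computed *from the zonal mean reflectances* (not per pixel and then
averaged), matching the standard zonal workflow.

**Predictors.** 47 per polygon: 5 bands, 35 registered indices
(`list_indices()`; closed forms frozen in `FORMULAS.md`), 6 soil
properties and slope. Slope comes from the DEM by Horn's 3x3 method, the
algorithm of the standard GIS slope tool; coarse soil rasters are
brought to the analysis grid by nearest-neighbor resampling, which
introduces no new values and so preserves the sand+silt+clay = 100
closure.

**Models.** MLR by ordinary least squares; RF via `ranger`
(`num.trees 500, mtry 11, max.depth 21`); XGB via `xgboost`
(`eta 0.05, max_depth 6, nrounds 200, subsample 0.7,
colsample_bytree 0.9, gamma 0.3`); GBR as plain gradient boosting,
realized through `xgboost` with the regularization terms disabled
(`lambda = alpha = gamma = 0`, no column subsampling, exact greedy
splits) and `eta 0.1, max_depth 5, nrounds 200, subsample 0.7`. These
hyperparameters are the tuned defaults of `model_config()`; a user can
override any of them. Accuracy is `R^2 = 1 - SS_res/SS_tot` about the
test-set mean and `RMSE = sqrt(mean(residual^2))` on a seeded 80:20
split.

**Feature selection.** `iterative_feature_selection()` repeats
fit / evaluate / drop: each round removes the single worst
variance-inflation-factor offender above the cut (default 10) and every
predictor below the importance floor (default 0.005; importances are
impurity/gain shares for ensembles and normalized absolute standardized
coefficients for MLR, so the loop is uniform across kinds). Selection
optimizes the *test* RMSE — faithful to the workflow being reproduced,
but optimistically biased; hold out a third split if an unbiased error
is needed.

**Comparison statistics.** Method RMSEs are compared by one-way ANOVA
with stages (or stage-by-seed replicates) as the error term, followed by
Fisher's LSD compact letters ('a' = highest mean). The contribution of
the five soil/terrain predictors (sand, silt, clay, OM, slope) is tested
by a one-tailed paired t-test of `reduced - full` RMSE over
(method, stage) pairs; identical vectors return the boundary p = 0.5.

## What the synthetic generator emulates

`scenario_config()` fixes the study conditions; all defaults are chosen
once to match the emulated field study and are not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `yield_mean` | 10.19 Mg/ha | field mean yield |
| `yield_cv` | 0.1211 | coefficient of variation of yield |
| `relief_m` | 8 m | total DEM relief, a diagonal ridge falling to the NE/SW corners |
| `transect_spacing` | 4.6 m | six-row combine header |
| `point_spacing` | 3.7 m | gives ~17 m^2 harvested per record |
| `yield_floor` | 1.5 Mg/ha | lower clip, matching the observed minimum scale |
| `n_stages`, `canopy_cover_by_stage` | 7 stages, 0.10-0.75 | V4 through V14/VT (DAP 20-83) |
| grid | 300 x 300 at 1 m | desk scale; tests use 60-320 |

Soil is two smoothly interlocking bodies (a heavy smectitic clay and a
siltier carbonatic clay) from a thresholded smoothed Gaussian random
field — the simplest structure with a distinct separation between two
soil series; texture fractions are renormalized to sum to exactly 100.
A latent vigor field
`standardize(w_soil * (0.5 z(OM) + 0.3 z(AWC) - 0.2 z(clay)) -
w_slope * z(slope) + noise)` drives both the canopy spectra and yield.
The vigor noise is deliberately plant-scale — essentially white at 1 m
pixels — not a field-scale pattern. This matters for the null scenario
below: any spatially smooth component of yield that is not carried by
the spectra can be proxied within a field by *any* smooth covariate,
soil rasters included, so a "no soil effect" scenario with smooth yield
noise is not actually null — a within-field test correctly detects the
proxy value and rejects far above its nominal level. With white
plant-scale noise (and footprint integration, next paragraph) the yield
of neighboring harvest records is uncorrelated under the null; the
residual miscalibration of the soil-inclusion test that remains even
then is a property of the test itself, not of the scenario — see
*Known limitations*.

Canopy reflectance mixes a healthy and a stressed canopy endmember by
`pnorm(vigor)`; bare pixels get a soil endmember. The three spectra are
documented constants in `inst/extdata/endmembers.yml`, chosen so the
registered indices span realistic ranges and so NDVIre is bimodal
(canopy 0.38-0.72 vs soil ~0.02) — the gap is what makes automatic
Otsu masking recover the generator's stored canopy mask. Canopy grows
outward from east-west planting rows by distance-ordered fill (a
morphological dilation), hitting each stage's cover fraction exactly and
nesting across stages.

Yield at each harvest point is
`yield_mean * (1 + yield_cv * response)` clipped at the floor. All
yield covariates (vigor, soil score, slope, clay) are integrated over
the record's rectangular harvested footprint
(`point_spacing x transect_spacing`, pixels partitioned between
neighboring records), because the combine weighs grain from the whole
footprint, not from the GPS centroid pixel; this is also what ties the
yield signal to the *zonal* spectral means, which integrate the same
area. Under `nonlinearity = "linear"` the standardized response is
`0.8 z_vigor + 0.5 w_soil z_soil + 0.5 w_slope z_slopebenefit + eps`
(`eps` iid, sd 0.5 before standardization); the realized coefficients on
the standardized covariates are stored in the `truth` attribute, so
ordinary least squares on the stored covariates must recover them within
sampling error — a test the suite runs at n > 5000. Under
`"threshold-interaction"` the response adds
`0.8 w_soil z_clay z_slope - max(-0.2 - z_vigor, 0)`: a clay-by-slope
interaction (waterlogging on heavy flat clay vs droughty steep clay) and
a low-vigor threshold penalty. The nonlinear part deliberately carries
weight comparable to the linear part — a token nonlinearity would not
create the regime the scenario exists to represent, one where linear
models underfit and tree ensembles do not.

**What the generator does not emulate.** No radiative transfer, no
weather/thermal-time dynamics, no plant-density variation, no yield
monitor artifacts (speed/pass delays are assumed already cleaned), no
georeferencing error, and stage-to-stage change is limited to canopy
cover. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that its statistical conclusions hold under
the stated generative assumptions — not that any particular accuracy
level transfers to a real field.

## Numerical choices and degenerate inputs

- Division by zero in any index yields nodata, never infinity, so zonal
  means stay finite; `NA` bands propagate.
- The HUE arccos cannot exceed 180 degrees; the standard HSI completion
  (`360 - theta` when blue > green) is applied; achromatic pixels get
  hue 0, saturation 0; an all-zero RGB triple is nodata.
- Red-edge position interpolates between the sensor's band centers
  (668, 717, 842 nm) and is clamped to [690, 750]; flat spectra are
  nodata. REIP differs from REP only in its inflection-level estimate
  (`(R + 2 RE + N)/4` vs `(R + N)/2`).
- Otsu thresholds use 256 equal-width bins over the finite range; a
  constant sample is an error, not a silent threshold.
- Ties in feature selection drop alphabetically; the Voronoi neighbor
  scan stops only when the next point provably cannot cut the cell.
- Rank-deficient MLR designs warn and zero the aliased coefficients.
- `compare_methods()` letters come from maximal LSD-overlap intervals on
  the sorted means; with a non-significant ANOVA every method shares
  'a'.
- All randomness flows through explicit seeds (`with_seed()` restores
  the caller's RNG state); identical configurations give byte-identical
  rasters, point sets and feature tables.
- In `evaluate_stage_models()` every stage's table is partitioned with
  its own seed (the run seed salted by stage position). Reusing one
  partition across stages would let a single split realization drive
  all (method, stage) cells at once, undermining the treatment of
  stages as replicates in the comparison statistics.

## Design decisions that were genuinely open

- **Roundness definition.** The isoperimetric ratio `P^2/(4 pi A)` is
  used (1 = circle). Near-square Thiessen cells score ~1.27, and the
  filter default (3) removes slivers. Other circularity conventions
  exist; the threshold is a config value, not a constant.
- **Mask semantics.** Masking could multiply rasters by the 0/1 mask;
  nodata semantics were chosen instead so that zonal means average
  vegetation pixels only (see above).
- **GBR backend.** Plain gradient boosting is expressed through
  `xgboost` with its regularized objective disabled rather than through
  a separate library; the test suite checks determinism and importance
  normalization, not backend identity.
- **ANOVA error term.** Growth stages (and, in the replicated study,
  stage-by-seed cells) serve as replicates for the method comparison;
  that is an interpretation, and it is stated wherever the letters are
  reported.
- **Null-scenario reduced set.** The soil-inclusion test drops
  sand, silt, clay, OM and slope (the five predictors whose joint value
  is under test); BD and AWC stay, mirroring the reduced-model
  definition being reproduced. Consequently the null scenario zeroes
  both the soil and the slope effect weight — leaving a live slope
  effect would make rejections correct rather than false.
- **Per-stage thresholds.** Manual per-flight mask thresholds are
  accepted via `mask_threshold`; Otsu is the automatic default since
  manual values are inherently dataset-specific.

## Problem sizes used by the tests and the acceptance script

Unit tests run on 30-120 m grids; the coefficient-recovery check uses a
320 x 320 m field (~5600 harvest points); the replicated comparison
study uses ten 100 x 100 m scenarios with five stages (15-75 % cover)
plus twenty matched null scenarios. These sizes were chosen so the full
suite completes in well under half an hour on one CPU while keeping
every sample large enough for the statistical checks — in particular,
five stages per scenario so the paired (method, stage) comparisons rest
on five independent partitions rather than one or two. They are the
package's desk-scale defaults; all of them scale up through
`scenario_config()`.

## Known limitations

- The Voronoi clipper requires a convex field boundary (rectangles in
  the shipped scenarios); concave boundaries would need a general
  polygon clipper.
- Rasters are exchanged as ESRI ASCII grids and points/polygons as
  CSV/GeoJSON; no GeoTIFF or shapefile I/O, and no reprojection —
  inputs are assumed co-projected and metric.
- Feature selection and the soil-inclusion comparison reuse the test
  split, as the reproduced workflow does; both are flagged as
  optimistically biased.
- **The soil-inclusion t-test is anti-conservative as a calibrated null
  test.** It compares a 47-predictor model with a 42-predictor model,
  and for these ensembles the removal of *any* five columns changes
  performance systematically: in a count-matched control experiment on
  no-soil-effect scenarios, dropping the five soil/terrain columns
  raised ensemble test RMSE by ~0.005-0.01 Mg/ha, while replacing them
  with five fresh iid-noise columns *lowered* it — the extra columns
  act as implicit regularization (feature-sampling diversity for the
  forests, split-dilution for the unregularized booster), independent
  of their content. The paired t-test reliably detects this capacity
  effect, so its false-rejection rate on no-soil-effect scenarios sits
  near 20-30 % rather than the nominal 5 %, roughly independent of
  field size (tested to 180 x 180 m). The test is therefore evidence
  about soil value only when the observed RMSE rise dwarfs the ~0.005
  Mg/ha capacity bias, as it does in the live-effect scenarios here
  (p < 1e-10); a calibrated alternative would compare against a
  count-matched noise control rather than plain removal.
- The 62-predictor count sometimes quoted for this kind of analysis is
  not reconstructible from the named index set (5 bands + 35 indices +
  6 soil + slope = 47 here); the registry is extensible and the gap is
  documented rather than guessed at.
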