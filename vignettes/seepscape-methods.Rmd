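---
title: "Methods: synthetic seep seascapes, terrain predictors and ensemble habitat models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic seep seascapes, terrain predictors and ensemble habitat models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seepscape)
```

`seepscape` studies how a seep-dwelling cold-water coral distributes itself
around active methane seepage at a single carbonate mound. This vignette is
the package's own account of the models it implements, the knobs that
matter, and the choices made where the design was genuinely open.

## The synthetic seascape and what it does (and does not) emulate

Field data for this problem — metre-scale AUV bathymetry, annotated
photomosaics, digitized seep features — are large and not redistributable,
so the package ships a generator that emulates their *structure* with known
ground truth:

* **Bathymetry**: a radially symmetric Gaussian mound (`mound_height`,
  default 20 m, on a ~1000 m-deep floor; width fixed at one sixth of the
  extent) plus a stationary Gaussian random field produced by spectral
  filtering of white noise (`noise_amplitude` 0.4 m,
  `noise_correlation_length` 8 m). The default grid is 256 x 256 cells of
  1 m, the resolution at which such surveys are typically gridded.
* **Features**: 8 carbonate disc patches (radii 3–8 m) in the central 56%
  of each axis (kept off the border so large terrain windows around
  occurrences remain valid). A fraction `seep_fraction` (0.6) of patches
  actively seep; each seeping patch hosts a random subset (each class with
  probability 0.7, at least one) of bacterial-mat, mussel and tubeworm
  blobs, constrained to lie within 3 m of carbonate. Random subsets matter:
  with all three classes on every patch the three indicator distance layers
  are numerically identical (r = 1.00); with subsets they come out strongly
  but imperfectly correlated, as successional seep stages are in real
  sites. Vesicomyid clams are not simulated; the indicator set is
  mats/mussels/tubeworms/carbonate.
* **Truth**: suitability
  `exp(-d_carb / 2 m) * (0.5 + 0.5 exp(-d_ind / 10 m))`, clipped to [0, 1].
  The two e-folding scales are the two response length scales the models
  should recover — a sharp requirement for hard substrate and a milder
  pull toward active seepage. The exact functional form is this package's
  convention and is echoed into `scene_config.json` on every pipeline run.
* **Occurrences**: cells drawn without replacement with probability
  proportional to suitability, one point per cell at the cell centre
  (mirroring deduplication of presences on the analysis grid); default 155.
* **Isotopes**: two-group normals with means/SDs matching the reported
  tissue values (active −26.2 ± 1.8 ‰ δ¹³C, transition −22.0 ± 0.2 ‰;
  δ¹⁵N 10.1 ± 1.3 vs 10.7 ± 0.2; group sizes 19 and 3), a +62 ‰ label
  uptake shift applied to active specimens with probability 1/3 (one
  responder in three incubated), and a −1.5 ± 1.0 ‰ handling drift
  otherwise.

What the generator does **not** emulate: anisotropic terrain, navigation
error, detection failure in imagery, clustered (overdispersed) occurrence
noise, fluid-flux chemistry, or any relationship between terrain and
feature placement beyond the border margin. Passing tests therefore show
the pipeline recovers planted signals of the right shape and scale — not
that it would behave identically on survey data.

Every generator is a pure function of its configuration, including the
seed; seeds are recorded in output metadata and all randomness inside one
pipeline run fans out from `master_seed`.

## Terrain predictors

All layers live on the bathymetry grid (row-major from the north-west
corner, half-open metric cells, distances between cell centres).

* **Slope/aspect** use Horn's 3 x 3 weighted differences. Aspect is the
  compass direction of steepest *ascent* (0° = grid north, clockwise), so a
  plane rising eastward has aspect 90°, eastness 1. Flat cells have
  undefined aspect; their northness/eastness are set to 0 so the layers
  stay defined wherever slope is.
* **BPI** at a metric scale is the cell elevation minus the mean over the
  annulus `1 cell < d <= scale` (10 m and 100 m by default). Values are
  kept in raw metres — the common GIS tool standardizes to integers, but
  raw values are transparent and strictly monotone in the same
  information. Whether the original analyses used an annulus or filled
  disc, standardized or not, is not documented; both radii are
  configurable and the default is the punctured disc above.
* **VRM** sums unit surface normals over a square window (25 m default)
  and reports `1 - |resultant| / n`; 0 on any plane, 0.293 on an ideal
  two-facet 45° checkerboard.
* **Curvature** comes from a least-squares quadratic fit to each 3 x 3
  window, reported as `-2(a + b)` per metre where `a`, `b` are the `x²`,
  `y²` coefficients: domes positive, bowls negative, planes 0. The
  plan/profile/total distinction is not documented for the original
  workflow; this total-curvature convention is recorded in the layer
  metadata.
* **Distances** to carbonate, mats, mussels and tubeworms are exact
  Euclidean distances between cell centres via a two-pass separable
  squared-distance transform, tested for exact equality against
  brute-force nearest-feature search.

Edge and nodata handling is uniform: 3 x 3 operators return nodata if any
neighbour is missing; windowed operators (BPI, VRM) use only valid cells
when at least 50% of the window is valid, else nodata. The predictor set
carries the union nodata mask, and any cell invalid in one layer is
excluded from all downstream sampling.

## Habitat classification

A 5 m fishnet partitions the site, anchored at the raster origin (the
original anchoring is undocumented; the raster origin makes the grid a
pure function of the data). A cell with at least one indicator cell centre
is *active*; carbonate without indicators is *transition*; otherwise
*none*. Occurrences inherit their cell's label; occurrences in *none*
cells are excluded from the active/transition percentage denominator and
reported separately. Nearest-indicator distances are point-to-cell-centre;
all SDs are sample (n − 1) SDs. Note the generator is not calibrated to
reproduce the field's *proportions* of active vs transition occurrences —
only the ordering of their distances to seepage (active ≪ transition),
which is asserted as an inequality in the tests.

## The ensemble habitat suitability model

The modelling pipeline is presence–background:

1. **Collinearity pruning** removes, iteratively, the variable with the
   largest mean |r| among any pair exceeding |r| > 0.7 — except members of
   a *keep set* that is never dropped. The default keep set is the four
   distance-to-seep-feature layers. The three indicator distances belong
   there as the successional-stage hypothesis set despite their mutual
   correlation; `d_carbonate` belongs there too because on this generator's
   geometry it correlates 0.6–0.8 with the indicator distances (indicators
   sit *on* carbonate), and a data-driven pruner that discarded the
   substrate variable would remove the very signal the study design aims to
   estimate. Retained keep-set pairs above threshold are logged with a
   warning.
2. **Background**: 5,000 cells drawn uniformly from the valid area,
   excluding presence cells, all points weighted equally.
3. **Spatial-block cross-validation**: 50 m square blocks assigned
   uniformly at random to 5 folds, re-drawn (bounded retries) until every
   fold holds a presence. Background points are assigned by location
   exactly like presences. Blocks decorrelate evaluation data from
   training data; the tests document that block CV is not more optimistic
   than random splits on this autocorrelated data.
4. **Learners** (settings logged in the run manifest; the originals are
   undocumented): random forest with 500 trees, default feature
   subsampling, minimum node size 1; gradient boosting with up to 1,000
   trees, learning rate 0.01, depth 3, exact greedy splits, early stopping
   on a 10% in-fold validation split. One model per (algorithm x fold) =
   10 runs.
5. **Evaluation**: AUC is the Mann–Whitney concordance with ties counted
   ½ (tested equal to trapezoidal ROC integration). TSS is the maximum of
   sensitivity + specificity − 1 over the threshold grid 0, 0.01, …, 1,
   scoring `score >= threshold` as positive and reporting the smallest
   maximizing threshold for reproducible ties.
6. **Permutation importance**: per run and variable, the mean over 99
   replicates of `1 - cor(original predictions, permuted-variable
   predictions)` on the held-out fold. If permuted predictions are constant
   while originals are not, the correlation is taken as 0 (importance 1);
   non-finite replicates are dropped from the mean with a count; constant
   original predictions give all-zero importances with a warning.
   Cross-model importance is the unweighted mean over the 10 runs.
7. **Ensemble**: cell-wise weighted mean of member predictions, weights
   proportional to TSS (runs with TSS ≤ 0 excluded; all-nonpositive TSS is
   an error). Being convex, the ensemble lies within the member range.
8. **Response curves** are evaluation strips: the focal variable sweeps
   its observed range over 100 points with all other variables at their
   training medians, averaged per algorithm.

## Numerical choices and degenerate inputs

* The distance transform uses a finite large sentinel instead of infinity
  so the parabola-envelope arithmetic never produces NaN.
* Windowed sums (BPI, VRM) are FFT convolutions; the affine-surface BPI
  test pins the numerical error below 10⁻⁹ m.
* An empty feature raster is an error for `distance_to()` (callers may
  substitute a constant far-distance layer); a seepless scene makes the
  indicator factor of the truth surface the constant 0.5.
* Single-record isotope groups report SD 0 with an explicit flag; Welch's
  t and the one-way ANOVA are computed from their closed forms with
  p-values from `pt`/`pf`, and are cross-checked in the tests against
  `t.test()` and `oneway.test()` — the +5 ‰ enrichment threshold cleanly
  separates the one label-assimilating specimen (Δ ≈ +62 ‰) from
  drift-scale changes (|Δ| < 3 ‰) and is configuration-exposed.

## Problem sizes used by the test suite

Unit and property tests run on small grids (16–96 cells a side) with
reduced BPI scales and VRM windows so every operator keeps valid interior
cells; the end-to-end checks run the full default scene (256 x 256 m, 155
presences, 5,000 background, 10 runs), and the importance-rank check
repeats the full pipeline over 10 seeds with 19 permutation replicates per
variable — enough for a stable *ranking*, while the per-run default stays
at 99 replicates for stable *values*. These sizes are the package's chosen
study conditions; enlarging them is a one-line configuration change.

## Known limitations

* No geodesic/projected-CRS handling: the grid is a local metric plane.
* No MaxEnt/GLM/GAM learners, no importance rescaling to sum 1, no
  extrapolation (MESS) masks, no automated block-size selection.
* ORP and temperature sensor layers are accepted as extra rasters but
  never synthesized.
* The isotope module carries δ values as plain ‰ numbers; no
  isotope-ratio conversion or mixing models.
* GeoTIFF is not written; rasters interchange as ESRI ASCII grids with a
  JSON metadata sidecar.
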