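# seepscape

Site-scale analysis tools for cold-water corals living on methane seeps.

Some octocorals settle not on the quiet periphery of seep sites but within
metres of active seepage, attached to authigenic carbonate beside bacterial
mats, bathymodiolin mussels and vestimentiferan tubeworms. `seepscape`
implements the quantitative workflow used to study that habitat association
at a single seep mound, end to end:

1. **Synthetic seascape generation** — a Gaussian seep mound with correlated
   roughness, carbonate patches, biogenic indicator features, a planted
   ("true") suitability surface
   `exp(-d_carb / 2 m) * (0.5 + 0.5 exp(-d_ind / 10 m))`, occurrence points
   sampled proportional to suitability, and synthetic isotope specimens —
   so the whole downstream pipeline is testable against known ground truth.
2. **Terrain and distance predictors** — slope, northness/eastness (Horn's
   method), bathymetric position index (BPI) at 10 m and 100 m scales,
   vector ruggedness (VRM, 25 m neighbourhood), total curvature from a
   local quadratic fit, and exact Euclidean distance-to-feature layers.
3. **Fishnet habitat classification** — a 5 m x 5 m grid over the site;
   cells holding at least one living seep indicator are *active*, cells
   with carbonate but no indicator are *transition*; occurrences inherit
   their cell's label and get nearest-indicator distances.
4. **Ensemble habitat suitability modelling (HSM)** — presence-background
   modelling with random forests and gradient boosting, Pearson |r| > 0.7
   collinearity pruning with a protected distance-layer hypothesis set,
   5,000 background points, 50 m spatial-block 5-fold cross-validation,
   rank-based AUC and the true skill statistic (TSS), permutation variable
   importance (mean over 99 replicates of `1 - cor(original predictions,
   permuted-variable predictions)`), a TSS-weighted ensemble suitability
   surface, and evaluation-strip response curves.
5. **Stable-isotope analysis** — group summaries (sample SD), Welch's
   t-test and one-way ANOVA from their closed forms, and enrichment
   classification for ¹³CH₄ labelling incubations (a specimen is enriched
   when its tissue δ¹³C shift exceeds +5 ‰). The six-specimen incubation
   table ships as a packaged fixture.

## Worked example

```r
library(seepscape)

# incubation table: transition-zone natives and label uptake
tab <- seep_table1()
s <- group_summary(tab, "transition", "native_d13c")
# transition native d13C: -22.04 +/- 0.23 permil (n = 3, range -22.21 to -21.78)
enrichment(tab, threshold = 5)$counts
#>             enriched
#> habitat      FALSE TRUE
#>   active         2    1
#>   transition     3    0

# synthetic scene -> predictors -> classification -> ensemble HSM
scene <- simulate_scene(scene_config(rng_seed = 1), n_occurrences = 155)
preds <- assemble_predictors(terrain_stack(scene$bathymetry),
                             distance_layers(scene$features))
net  <- build_fishnet(raster_extent(scene$bathymetry), cell = 5)
occ  <- classify_occurrences(scene$occurrences, classify_cells(net, scene$features))
nearest_indicator_distance(occ, scene$features)$summary
#>          class   n  pct mean_dist sd_dist
#> 1       active  28 21.7      1.48    1.29
#> 2   transition 101 78.3     11.13   15.54
#> ...

fit <- run_hsm(scene$occurrences, preds, hsm_spec(rng_seed = 1))
fit
#> <hsm_result> 10 runs (rf + gbm), 8 predictors
#>   mean AUC 0.980, mean TSS 0.947
```

Occurrences in *active* cells sit far closer to seep indicators (1.5 m
mean) than those in *transition* cells (11 m mean), and the block
cross-validated ensemble recovers the planted carbonate-distance signal:
`fit$importance` ranks `d_carbonate` first by a wide margin, and the
`response_curve()` for `d_carbonate` peaks within the first 2 m.

A full pipeline run with manifests and file outputs:

```r
run_pipeline(default_config(master_seed = 1), output_dir = "out")
```

or from a shell via the thin wrapper `inst/scripts/seepscape`.

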