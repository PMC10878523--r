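# firescape

Fire-history reconstruction from multidecadal optical satellite time series,
and assessment of what those fires did to forest structure as seen by
spaceborne lidar.

## The problem

Dry tropical forests can be transformed by a handful of fires: an initial
burn removes most of the canopy, the scar re-burns within a few years, and
recovery — if any — is too slow to measure over a satellite era. Managers
and ecologists need two reconstructions from the archive: a dated map of
every burn over ~40 years of monthly imagery, and an estimate of how plant
area index (PAI), canopy cover (CC) and canopy height (CH) respond to the
number of fires and the time since the last one.

firescape implements that workflow for anyone working with
Landsat-class reflectance composites and GEDI-class lidar footprints, and —
because such archives are too large to ship — includes a seeded synthetic
scene generator with a ground-truth fire catalog so the entire pipeline is
testable end to end.

## The method

Per forest pixel, the monthly NDVI series is decomposed BFAST-style into
harmonic seasonality plus a piecewise-linear trend,

y_t = trend_j(t) + Σ_{k≤K} [ a_k sin(2πkt/12) + b_k cos(2πkt/12) ] + ε_t,

with breakpoints placed by an exact dynamic-programming RSS search and the
break count chosen by BIC. The fire rule classifies a pixel as burned when a
**negative trend break** coincides with a **dNBR ≥ 0.2** (dNBR = NBR_pre −
NBR_post) within the 95% confidence interval of the break date. Burned
pixels group into dated event polygons (rook contiguity, 5-ha minimum
mapping unit), perimeters are refined by object-based classification (SLIC
segmentation + a small feed-forward network) of the differenced NDVI image
around the fire month, and events accumulate into burn-count,
time-since-fire and max-dNBR layers. Lidar footprints join those layers at
their acquisition date and are analyzed with Kruskal–Wallis tests, Dunn
post-hoc comparisons (Bonferroni) and linear mixed models
`metric ~ n_fires + n_months + (1|season) + (1|zone)`.

See `vignettes/fire-history-methods.Rmd` for the model, parameter defaults,
and the design decisions behind the break detector and the refinement step.

## Worked example

```r
library(firescape)

cfg <- scene_config(seed = 1)          # 100 x 100 px, 1985-2022, six fires
run <- run_pipeline(pipeline_config(scene = cfg), quiet = TRUE)
evaluate_against_truth(run, run$truth)
#> <evaluation> precision 1.000  recall 1.000  (6/6 matched)
#>   fire-month error: mean abs 0.00, max abs 0

run$summary$landscape
#>   burn_count area_ha     fraction
#> 1          0  370.26 0.6802248677
#> 2          1   91.71 0.1684854497
#> 3          2   47.25 0.0868055556
#> 4          3   34.56 0.0634920635
#> 5          4    0.54 0.0009920635

run$stats$recovery[, c("response", "effect", "estimate", "p", "label")]
#>   response   effect      estimate            p     label
#> 1      pai  n_fires -0.2177202802 1.504541e-07 declining
#> 2      pai n_months -0.0009090430 6.129701e-01      flat
#> 3       cc  n_fires -0.0705579287 3.146112e-32 declining
#> 4       cc n_months -0.0002452582 2.035798e-01      flat
#> 5       ch  n_fires -0.1044126962 1.632270e-03 declining
#> 6       ch n_months -0.0395864525 4.472635e-64 declining
```

Reading the output: all six scheduled fires are found at the correct month
with no false events; about a third of the forest burned at least once, with
repeatedly burned cores; fire count significantly depresses all three
structure metrics (the per-fire PAI slope of ≈ −0.22 recovers the
generator's −0.2) while months-since-fire shows no recovery for PAI or
canopy cover — canopy height keeps declining slowly as fire-killed trees
fall (estimated −0.040 m per month against a generator truth of −0.041).

The same stages run on real data by passing your own `archive`,
`footprints` and training labels to `run_pipeline()`, or stage by stage via
`forest_base_map()`, `scan_breaks()`, `detect_fires()`,
`accumulate_history()` and `filter_and_attach()`. A thin command-line front
end lives at `inst/cli/firescape.R`
(`Rscript firescape.R all --config cfg.yaml`).

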