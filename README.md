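# rsei

Entropy-weighted Remote Sensing Ecological Index (RSEI) with
moving-window weights, for Landsat-8-like multiband scenes.

## The problem

The RSEI summarizes urban ecosystem quality from satellite imagery as a
single 0–1 score per pixel (higher = better). The classical
formulation combines four indicators — greenness (NDVI), wetness
(tasseled-cap), dryness (NDBSI) and heat (LST) — through the first
principal component of a PCA, which imposes one fixed loading vector on
the whole scene, varies arbitrarily between scenes and years, and
traditionally excludes water.

This package implements an improved formulation for urban monitoring:

- **six indicators**: a composite vegetation index
  CVI = NDVI × EVI × SAVI, tasseled-cap Wetness, NDBSI (dryness),
  the impervious surface index ISI = (NDBI − NDVI)/(NDBI + NDVI),
  the urban index UI, and land surface temperature retrieved from the
  thermal band by the single-channel method
  LST = T_B / (1 + (λ T_B / ρ) ln ε) − 273.15;
- **objective entropy weights**: after min–max normalization
  (forward for CVI and Wetness, inverse for NDBSI, ISI, UI, LST) each
  indicator's information entropy
  E_j = −(ln n)⁻¹ Σᵢ P_ij ln P_ij is computed over an occupied-bin
  histogram, and weights W_j = (1 − E_j)/(m − Σ E_j) reward indicators
  with stronger spatial differentiation;
- **a moving window** (133 × 133 pixels by default) inside which the
  entropy weights are recomputed, so the weighting adapts to local
  landscape structure:
  RSEI(i,j) = Σ_k W_k(i,j) · Y_k(i,j).

Around the index the package provides the evaluation toolkit used in
urban-ecology studies: five-class quality maps, global Moran's *I* with
permutation inference, Getis-Ord Gi\* hot/cold-spot classification,
pixel-sampled two-way ANOVA (group × year) with Tukey post hoc and
compact-letter summaries, and ECDF export — plus a synthetic
Landsat-8-like scene simulator so every part is testable without
satellite downloads. The PCA baseline is included for comparison.

It is written for remote-sensing ecologists and urban-sustainability
researchers who want a reproducible, scriptable RSEI pipeline.

## Worked example

```r
library(rsei)

# a 128 x 128 synthetic Landsat-8-like scene: vegetation / water /
# built-up / bare-soil patches, thermal band, nodata holes
scene <- generate_scene(scene_config(grid_shape = c(128, 128), seed = 42))

res <- compute_rsei(scene, window_size = 33)
res
#> <rsei_result> model improved_entropy, 128 x 128, mean RSEI 0.3442
glance(res)
#> # A tibble: 1 x 6
#>   model            mean_rsei sd_rsei min_rsei max_rsei n_valid
#> 1 improved_entropy     0.344   0.202    0.106    0.802   15990
tidy(res)          # five-class quality table
#>   class label     count  fraction
#> 1     1 Very poor  7420 0.464
#> 2     2 Poor       2426 0.152
#> 3     3 Moderate   3404 0.213
#> 4     4 Good       2739 0.171
#> 5     5 Very good     1 0.0000625

ev <- evaluate_rsei(res, n_permutations = 199, seed = 42)
ev$moran
#> Moran's I = 0.9199 (E[I] = -0.0001), one-sided p = 0.005 (199 permutations, n = 15990)
```

The mean RSEI of 0.344 says the scene (35% built-up) sits between
"poor" and "moderate" ecological quality; 46% of pixels fall in the
lowest class. Moran's *I* of 0.92 shows ecological quality is strongly
spatially clustered, as expected for a patchy urban landscape — like
values form contiguous hot and cold neighbourhoods rather than being
scattered. `autoplot(res)` maps the index; `autoplot(res, "classes")`
maps the five classes.

Multi-year comparisons mirror a two-city study design:

```r
h   <- generate_history(history_preset("monotone_decline"), scene_config(seed = 1))
ev  <- evaluate_history(h, window_size = 33)      # mean RSEI, Moran, hotspots per year
cmp <- compare_histories(list(a = ev, b = ...), groups = c(a = "non-100RC", b = "100RC"))
cmp$anova                                          # two-way ANOVA + compact letters
```

## Command line

`inst/cli/rsei.R` exposes the pipeline as subcommands
`synth | indices | rsei | stats | compare`, each writing its outputs
plus a YAML config echo for provenance:

```sh
Rscript inst/cli/rsei.R synth --out scenes --preset monotone_decline --seed 1
Rscript inst/cli/rsei.R rsei  --input scenes/scene_2016.tif --out out --window-size 33
Rscript inst/cli/rsei.R stats --input out/rsei.tif --out stats
```

Rasters are written as 32-bit TIFF with a JSON sidecar carrying the
geotransform, CRS, band ranges and nodata mask.

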