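---
title: "Methods: entropy-weighted moving-window RSEI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-weighted moving-window RSEI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsei)
```

This vignette documents the model implemented by `rsei`, the choices
made where the design was genuinely open, and what the synthetic test
bed does and does not establish about real imagery.

## The index

The Remote Sensing Ecological Index condenses multiband reflectance
and thermal observations into one per-pixel score in $[0, 1]$, larger
meaning ecologically better. The classical construction takes the
first principal component of four normalized indicators — greenness
(NDVI), wetness, dryness (NDBSI) and heat (LST) — and rescales
$1 - \mathrm{PC1}$ to $[0, 1]$. Its known weaknesses are a single
scene-wide loading vector, loadings that flip between scenes and
years, an unguaranteed PC1 variance share, and the traditional
exclusion of water.

The improved formulation implemented here replaces the PCA with
objective entropy weights over six indicators:

* **CVI** $= \mathrm{NDVI}\times\mathrm{EVI}\times\mathrm{SAVI}$ —
  vegetation synergy: the product rewards pixels where greenness,
  canopy responsiveness and the soil-adjusted signal agree.
* **Wetness** — the tasseled-cap linear combination
  $0.1509 B_2 + 0.1973 B_3 + 0.3279 B_4 + 0.3406 B_5 - 0.7112 B_6 - 0.4572 B_7$.
* **NDBSI** — mean of the built-up index $(B_6-B_5)/(B_6+B_5)$ and the
  soil index $(B_6-B_7)/(B_6+B_7)$.
* **ISI** $= (\mathrm{NDBI}-\mathrm{NDVI})/(\mathrm{NDBI}+\mathrm{NDVI})$
  — impervious surfaces.
* **UI** — urban intensity; by default the printed SWIR1/NIR form
  (identical to NDBI), see "Open choices".
* **LST** — single-channel retrieval
  $T_B / (1 + (\lambda T_B/\rho)\ln\varepsilon) - 273.15$ °C, with
  $\lambda = 10.8\,\mu$m (stored in metres so $\lambda T_B/\rho$ is
  dimensionless) and $\rho = 1.438\times10^{-2}$ m·K. Radiance input
  is first converted to brightness temperature
  $T_B = K_2 / \ln(K_1/L + 1)$ with the Landsat-8 band-10 constants
  $K_1 = 774.8853$, $K_2 = 1321.0789$ (overridable).

Each indicator is min–max normalized over the scene's valid pixels,
forward $(X - X_{\min})/(X_{\max} - X_{\min})$ for CVI and Wetness
(more is better) and inverse for NDBSI, ISI, UI and LST (more is
worse), so all six point the same way. The information entropy of
indicator $j$,
$E_j = -(\ln n)^{-1}\sum_i P_{ij}\ln P_{ij}$,
is computed from an equal-width histogram on $[0,1]$; $n$ is the
number of occupied bins and $P_{ij}$ the frequency share of bin $i$.
Weights are $W_j = (1-E_j)/(m - \sum_j E_j)$: an indicator whose
values concentrate (low entropy, strong spatial differentiation)
carries more weight. The index is the per-pixel convex combination
$\mathrm{RSEI}(i,j) = \sum_k W_k(i,j)\,Y_k(i,j)$, which is guaranteed
to stay within $[0,1]$.

**Moving window.** Weights are recomputed inside square windows so the
weighting adapts to local landscape structure. Windows are anchored on
a stride grid, clamped (shrunk, never mirrored — mirroring would
fabricate spectra) at the borders, and each pixel's weights are
bilinearly interpolated between the four surrounding anchors, then
renormalized to sum to one. An exact per-pixel sliding mode, with
every pixel weighted from its own centred window and no interpolation,
is retained as the correctness reference and used by the tests; the
strided mode exists because a 133-pixel window evaluated at every
pixel would dominate runtime at no benefit — anchor weights vary
smoothly at the stride scale. Windows whose jointly-valid fraction
falls below 25% inherit the global scene weights; a window at least as
large as the raster degrades to global weighting with a notice.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_size` | 133 | pixels | balances local sensitivity and cost at Landsat's 30 m resolution (≈ 4 km neighbourhood) |
| `stride` | `window_size/4` (33) | pixels | anchor spacing for interpolation; 1 reproduces exact sliding |
| `bin_count` | 256 | bins | entropy histogram resolution; see "Open choices" |
| `clip_percentiles` | `c(0.01, 0.99)` in the pipeline | quantiles | robust normalization bounds; see below |
| `max_cloud` | 0.05 | fraction | scenes with ≥ 5% cloud are dropped before compositing |
| SR gain/offset | 2.75e-5, −0.2 | — | Landsat Collection-2 reflectance rescaling |
| emissivity | NDVI-threshold mode | — | per-pixel ε from cover classes; fixed mode for tests |
| `scheme` | queen | — | 8-neighbour contiguity for Moran/Gi\*; rook available |
| `n_permutations` | 999 | — | one-sided Moran permutation inference |
| `anova_n` | 2000 | pixels/cell | sampling density of the pixel ANOVA |

## Numerical choices

* **Entropy histogram.** "Number of different values" is
  operationalized as occupied histogram bins (256 equal-width bins on
  $[0,1]$): raw unique-value counting degenerates for continuous
  rasters, where essentially every pixel is unique and the entropy
  saturates at 1 regardless of structure. A single occupied bin gets
  $E_j = 0$ (zero-uncertainty limit; the $\ln 1$ division is otherwise
  undefined). If every $E_j = 1$, the weight formula is singular and
  equal weights $1/m$ are used.
* **Robust normalization (pipeline default).** ISI is a ratio whose
  denominator $\mathrm{NDBI}+\mathrm{NDVI}$ crosses zero on noisy
  water pixels; on any scene containing water the raw ISI range can
  stretch by orders of magnitude. Min–max normalization over such a
  range collapses the indicator to a near-constant grid whose
  spuriously low entropy then earns it a dominant weight — inverting
  the index's response to urbanization. `compute_rsei()` therefore
  normalizes between the 1st and 99th percentiles (values beyond them
  clamp to 0/1). The `normalize_indicator()` operation itself defaults
  to the exact min–max form, and the identity
  $\mathrm{forward}(X) + \mathrm{inverse}(X) = 1$ holds exactly there.
* **Division guards.** Normalized-difference denominators smaller than
  $10^{-12}$ in magnitude yield nodata rather than infinities.
* **Class boundaries.** The five quality classes are left-closed,
  right-open — $[0,0.2)$ very poor through $[0.6,0.8)$ good — with the
  top interval $[0.8,1]$ closed, so 0.2 is "poor" and 1.0 is "very
  good".
* **PC1 sign.** An eigenvector's sign is arbitrary; the baseline
  orients PC1 so the NDVI loading is negative, which makes
  $1-\mathrm{PC1}$ increase with greenness. PCA on rasters beyond
  200,000 valid pixels is fitted on a seeded subsample (scores are
  still produced everywhere).
* **Emissivity.** The NDVI-thresholds scheme uses ε = 0.991 for water
  (NDVI < 0), 0.966 for bare soil (0 ≤ NDVI < 0.2), 0.990 for dense
  vegetation (NDVI > 0.5), and $0.986 + 0.004 P_v$ with
  $P_v = ((\mathrm{NDVI}-0.2)/0.3)^2$ for mixed pixels. The mixed-pixel
  slope is deliberately small: any scheme must keep ε ≤ 1 at full
  vegetation cover, which rules out steeper interpolations sometimes
  seen in print.
* **Raster storage.** With no GeoTIFF writer available to the package,
  scenes are stored as multi-page 32-bit TIFF plus a JSON sidecar
  (geotransform, CRS, band names, per-band ranges, nodata). Samples
  are range-scaled, so round trips are accurate to about $2^{-32}$ of
  each band's range — far below sensor noise — but are not bit-exact
  for arbitrary doubles.

## Open choices

* **UI formula.** The SWIR1-based urban index printed in the source
  literature is algebraically identical to NDBI; part of the urban
  remote-sensing literature instead uses SWIR2. Both are provided
  (`ui(variant = "swir2")`); the printed form is the default for
  fidelity, which means UI and NDBI enter the six-indicator set as
  duplicated information — the entropy weighting then simply shares
  their joint weight.
* **Window weight assignment.** Whether local weights should be
  interpolated between windows or inherited from disjoint tiles is
  unspecified in the literature this follows; interpolation avoids
  blocky weight discontinuities and the exact sliding mode bounds the
  approximation in tests.
* **Cloud screening** uses scene-level metadata by default (an
  AOI-local fraction can be supplied); **the traditional baseline**
  runs unmasked (no water mask), matching the comparison design.

## The synthetic test bed

`generate_scene()` emulates a Landsat-8 surface-reflectance stack:
spatially coherent cover patches (vegetation, water, built-up, bare
soil) from quantile-thresholded Gaussian-smoothed seeded noise,
per-class mean spectra from a documented fixture table
(`default_class_spectra()`, invented but physically plausible: water
dark in the infrared, vegetation NIR-bright, built-up SWIR-bright and
warmest), additive Gaussian reflectance noise (sd 0.02) clipped to
$[0,1]$, brightness temperature with 1 K noise, and smoothed-noise
nodata holes. `history_preset()` provides five-epoch land-cover
trajectories — monotone built-up growth 0.2 → 0.6, a boom–bust path
0.2, 0.5, 0.3, 0.3, 0.6, and a stable control — with water and bare
soil held fixed and vegetation absorbing the complement; epoch seeds
derive from one base seed.

What this does *not* emulate: mixed pixels and gradual class
boundaries, seasonal phenology, atmospheric residuals, sensor
striping, correlated (non-white) noise, real cloud geometry, and
topography. Passing tests therefore demonstrate the correctness and
qualitative behaviour of the algorithms — not calibrated agreement
with any real city's values.

Problem sizes: unit tests use 40–128 pixel grids; the acceptance
checks use 50 synthetic scenes at 48², calibration simulations with
200 replicates, power simulations at 2000 pixels per ANOVA cell, and
full preset histories at 128². These sizes were chosen so the entire
suite runs in well under a minute per module while leaving every code
path exercised.

## Known limitations

* **Gi\* is scene-relative.** Hot/cold spots are defined against the
  scene's own mean and variance. While degraded cover is a minority,
  its growth expands the significant cold-spot area; once it becomes
  the scene majority, the mean moves into the degraded class and the
  global variance is inflated by the remaining high-value patches, so
  majority-class pixels stop being locally anomalous and the
  significant cold-spot *count* collapses even as the degraded *area*
  keeps growing (the fraction of negative Gi\* z-scores keeps rising).
  Cold-spot counts are therefore not a monotone proxy for degradation
  across large compositional shifts — compare them jointly with the
  mean RSEI trajectory.
* **Pixel ANOVA is pseudo-replicated.** Pixels are spatially
  autocorrelated, so treating sampled pixels as independent replicates
  overstates the effective sample size; p-values describe the sampled
  scenes, not a superpopulation. Sampling density is a config knob.
* **Entropy weighting rewards concentration.** An indicator made
  near-constant by an artefact (saturation, range collapse) is
  indistinguishable from one that is genuinely spatially
  differentiated; the percentile-clipped normalization exists
  precisely to keep ratio-indicator outliers from manufacturing such
  concentration.
* The package performs no reprojection (grids must match), no
  atmospheric correction beyond the linear SR rescaling, and no
  split-window LST.
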