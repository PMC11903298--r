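---
title: "Measuring oil-palm plantation efficiency from multispectral composites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring oil-palm plantation efficiency from multispectral composites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(palmwatch)
```

## The measurement problem

Plantation efficiency -- the fraction of a plantation's area actually under
oil-palm canopy -- is a production quantity that producers do not publish.
It can, however, be measured from space: 13-band multispectral imagery at
10--60 m resolution distinguishes mature palm canopy, immature plantings,
other vegetation, bare soil and water by their reflectance signatures.
`palmwatch` implements that measurement chain end to end:

1. **Cloud-free annual compositing** of repeated captures of one tile,
2. **up-sampling** of the 20 m and 60 m bands onto the common 10 m grid,
3. **unsupervised k-means classification** in 13-band reflectance space,
   with cluster centroids fitted once and then *frozen* so that yearly
   classifications are comparable,
4. **zonal extraction** of per-plantation palm coverage and of the NDVI,
   NDMI and BSI control indices,
5. **panel analysis**: random-intercept models of coverage with year
   indicators per certification cohort, plus Kruskal--Wallis and Dunn
   comparisons across plantation types.

Because the real rasters are tens of gigabytes, the package ships a
synthetic-scene generator with exact per-pixel ground truth. Every stage is
validated against that truth; the generator is first-class, tested code.

## Compositing and the delta cloud filter

A tropical tile is rarely cloud-free in any single capture, so an annual
composite is assembled from several near-simultaneous captures. Two
screens are applied before merging:

* the **provided cloud mask** of each capture (the analogue of an
  L2A scene-classification mask), which is imperfect by construction;
* the **delta filter**: for each pixel and reference band (B02, B04), the
  median across the captures *not already flagged by the provided masks*
  forms a consensus; a capture whose value exceeds the consensus by more
  than `tau` (default 0.12 reflectance) is flagged as residual cloud.

Two details matter. The deviation is *signed*: clouds brighten the visible
bands, and a symmetric (absolute) rule flags the one clean capture whenever
a majority of captures is cloudy at a pixel and a mask misses one of them,
which locks the cloud into the composite. Restricting the consensus to
mask-passed values has the same motivation. Second, the union mask is
**dilated by 3 pixels** before merging: a partially clouded 20 m cell
contaminates the up-sampled values of its clean 10 m neighbours (one 20 m
cell plus the bilinear interpolation reach is 3 px), a standard reason to
grow cloud masks in production processors.

Unmasked values are merged per pixel and band by the **median**; the mean
would be pulled by any residual contamination. Provenance counts the
contributing captures; pixels never observed cloud-free are nodata
everywhere. Nodata is `NA` and propagates through all arithmetic: any
bilinear stencil touching a nodata cell yields nodata.

Up-sampling uses a linear (bilinear) kernel with pixel-centre registration
and edge clamping, so constants are preserved exactly and the 2x and 6x
ratios reproduce hand-computable weights.

The 15-day window for "near-simultaneous" and `tau = 0.12` are free
parameters of the method, exposed in configuration.

## Land-cover model

A single k-means model (default `k = 8`, Lloyd iterations, features = raw
reflectance of all 13 bands, unstandardized) is fitted on a seeded
subsample of up to 100,000 valid pixels of one designated composite.
Initialization is seeded k-means++ with 10 restarts, keeping the lowest
inertia -- deterministic given the seed, and robust against seeding
centroids on outlier (residual-cloud) pixels, which a farthest-point rule
does systematically. `k = 8` leaves room for the four reported cover
groups plus within-class heterogeneity; four labeled categories require at
least `k = 4`.

Labeling clusters into {mature palm, immature palm, other vegetation,
other} is a human step in the original workflow; it is externalized here
as configuration (`label_clusters()`), with `label_clusters_by_truth()`
standing in on synthetic scenes (majority ground-truth class per cluster).

Classification applies the frozen centroids by nearest Euclidean distance;
ties -- including floating-point near-ties -- break to the lowest cluster
index, making the classification a pure function of (composite, model).
Coverage is the fraction of valid in-polygon pixel centres classified as
palm; following the published coverage figures it includes mature *and*
immature palm by default, with a mature-only switch (the original text is
ambiguous between the two).

## Spectral indices and zonal statistics

NDVI = (B08 - B04)/(B08 + B04), NDMI = (B08 - B11)/(B08 + B11),
BSI = ((B11 + B04) - (B08 + B02))/((B11 + B04) + (B08 + B02)), computed on
the up-sampled 10 m composite. A vanishing denominator yields nodata
rather than a clamped value, since it only occurs on degenerate pixels.
Zonal statistics use unweighted means over pixels whose *centres* fall
inside the polygon (even-odd ray casting) -- deterministic and
oracle-checkable, unlike area-weighted schemes. Annual pooled index tables
can be plantation-weighted (default) or pixel-weighted; the source
material does not say which was used.

## Panel models

The plantation-year panel regresses coverage on type indicators (own
estate, outside-supplier estate; small-grower is the omitted baseline),
the three index means, the annual Dec-31 palm-oil price, and year
indicators with 2018 as reference, with a random intercept per plantation.
Estimation is **maximum likelihood**, not REML, because log-likelihoods,
AIC and BIC are compared across nested specifications. p-values are Wald
z, two-tailed. Marginal and conditional R-squared follow the
variance-partition formulation: fixed-effect variance over total, and
fixed plus random over total.

One identification detail is inherited deliberately: the price is constant
within a year, so with a full set of year indicators the design is rank
deficient. The fixed-effect matrix is QR-pivoted and trailing aliased
columns are dropped with their names recorded -- in the standard seven-year
layout that is exactly the final year's indicator, matching the published
table, which likewise reports no indicator for the last year. The
synthetic panel generator therefore defines its truth with the final-year
effect at zero, so the fitted model is correctly specified.

Kruskal--Wallis uses the tie-corrected H with a chi-squared reference
(df = groups - 1); Dunn's post-hoc z uses pooled mid-ranks with the same
tie correction, positive when the first group of a pair has the larger
mean rank, unadjusted two-tailed p-values by default and an optional Holm
switch (no adjustment is named in the source analysis).

## What the synthetic generator emulates -- and what it does not

`generate_scene()` draws a patch mosaic of the five cover classes by
seeded Voronoi tessellation *on the 60 m block grid*, expanded to 10 m.
Aligning class boundaries with the coarsest native cells mirrors the
block layout of managed plantation landscapes and keeps the generated
20 m / 60 m band values representable: a class edge inside a 20 m cell
creates mixed spectra that no 10 m classification could unmix, which is a
property of real imagery but not a property any recovery test can
condition on. Class spectra are typical published reflectance levels for
tropical canopy, soil and water (configuration, not ground truth), with
strong separation in the native-10 m bands where canopy density expresses
itself most. Gaussian within-class noise (sd 0.012) is added per capture;
reflectances are clipped to [0, 1].

Clouds are soft-edged random ellipses, independent per capture, blended
towards a bright cloud spectrum; the provided masks miss 10% of truly
cloudy pixels by default, so the delta filter has residual clouds to
catch. How many residual clouds survive real L2A masks is unknown; the
10% is a free parameter, not an inference. Five captures per tile-year at
3-day spacing is conservative relative to the roughly 15-20 real captures
that enter an annual tile composite.

Default per-year conditions for the multi-year series convert 4% of the
initial mature-palm blocks to bare soil per elapsed year -- a decline
whose size is known exactly from the truth grids.

`generate_panel()` draws balanced plantation-year panels from the exact
linear mixed model the estimator assumes (type shares 28/39/77 of 144,
index regressors near the synthetic-scene levels, price from the fixed
annual table anchored at the printed 1940 MYR/t trough in 2018 and
5046 MYR/t peak in 2021, default effect pattern mirroring the published
magnitudes, random-intercept sd 0.10, residual sd 0.05, all in coverage
fraction units). Coverage is left unclipped, as a linear response.

Passing recovery tests on these scenes therefore shows that the pipeline
is *internally correct*: it recovers a truth that satisfies its own
assumptions. It does not show robustness to topography, BRDF, atmospheric
residuals, cloud shadows, sub-block land-cover mixing, phenology, or
model misspecification in the panel -- none of which the generator
emulates.

One empirical caution surfaced by the synthetic workflow: when the index
regressors are measured from the same scenes as coverage, land conversion
moves indices and coverage together, and the index coefficients absorb
most of the injected decline, leaving the year indicators small. The
year-effect power and null-calibration checks are therefore run on the
panel generator, where regressors and year effects are independent by
construction.

## Numerical choices and degenerate inputs

* Nodata is `NA` end to end; any contaminated stencil, zero denominator,
  or provenance-0 pixel is nodata, never a filled value.
* Nearest-centroid and k-means ties break to the lowest index; distance
  near-ties within 1e-12 are treated as ties for reproducibility across
  BLAS implementations.
* Empty k-means clusters are re-seeded from the farthest point.
* `kruskal_wallis()` refuses all-identical values (the tie correction is
  degenerate) and empty groups; `fit_random_effects()` requires at least
  two plantations and two years and reports which aliased columns it
  dropped.
* Every random draw flows from an explicit integer seed through a
  restore-on-exit RNG scope, so identical configurations are bitwise
  reproducible.

## Problem sizes

The bundled study sizes keep a complete run on one CPU comfortably inside
a coffee break: 120 x 120 px scenes (144 ha at 10 m), 5 captures per year,
7 years, 12 plantations; k-means on up to 100,000 pixel vectors; panel
simulations at 96-200 plantations with 100 power replicates and 400 null
replicates. The analysis scripts under `analysis/` and
`scripts/acceptance.R` run these exact sizes.

## Known limitations

* Cloud shadows are not modeled or screened (only brightening is).
* The B10 cirrus band is carried but not used for screening.
* Coverage at 10 m cannot see young or sparsely planted palms -- the
  immature class is a spectral, not an age, category.
* The panel model is associational; no causal identification
  (difference-in-differences, matching) is attempted.
* Real-data coefficient values from the original study are not
  reproducible without its archived rasters and are not targets here.
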