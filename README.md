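# palmwatch

Satellite-based measurement of **oil-palm plantation efficiency** — the
fraction of a plantation's area under palm canopy — and panel analysis of
how it evolves around sustainability-certification events.

Producers do not publish per-plantation efficiency, but 13-band
multispectral imagery resolves it at 10 m. The package implements the full
measurement chain and its statistical analysis:

* **Cloud-free annual composites** from repeated tile captures: provided
  cloud masks, plus a *delta filter* that flags residual cloud wherever a
  capture's visible reflectance exceeds the cross-capture median consensus
  by more than τ, then a per-pixel median merge. All 20 m / 60 m bands are
  up-sampled to the 10 m grid with a linear kernel.
* **Frozen-centroid k-means land cover**: one k-means model (k = 8, Lloyd,
  raw 13-band reflectance) fitted once, labeled into {mature palm,
  immature palm, other vegetation, other}, then reapplied unchanged to
  every tile-year so coverage is comparable across years.
* **Spectral indices** as environmental controls, with polygon zonal means
  at pixel centres:

  NDVI = (B08 − B04)/(B08 + B04)  NDMI = (B08 − B11)/(B08 + B11)
  BSI = ((B11 + B04) − (B08 + B02)) / ((B11 + B04) + (B08 + B02))

* **Panel models**: coverage ~ type dummies (small-grower baseline) +
  NDVI + NDMI + BSI + annual price + year dummies (2018 reference), with a
  plantation random intercept, fitted by ML; Wald z p-values,
  variance-partition marginal/conditional R², AIC/BIC; Kruskal–Wallis and
  Dunn post-hoc comparisons of coverage across plantation types.
* **A synthetic-data generator** producing multispectral scenes with exact
  per-pixel ground truth and plantation-year panels with known
  coefficients, so every stage is testable without any download.

## Worked example

The `analysis/` scripts run the whole study on a synthetic seven-year
landscape (120 × 120 px, 12 plantations, a 4 %/year conversion of mature
palm blocks to bare soil injected from 2019):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_composite.R
Rscript analysis/03_landcover.R
Rscript analysis/04_indices.R
Rscript analysis/05_panel_models.R
```

Stage 3 reports how well measured coverage tracks the ground truth:

```
Coverage extracted for 84 plantation-years; max |error| vs truth: 0.0055
Annual mean coverage (measured vs truth):
  year coverage truth_coverage
1 2017    0.696          0.696
2 2018    0.683          0.684
...
7 2023    0.613          0.613
```

i.e. the classification recovers the injected decline (0.696 → 0.613 mean
coverage) with a worst per-plantation error of half a coverage point.
Stage 5 fits the cohort model and runs the type comparison:

```
Kruskal-Wallis chi-squared = 17.016, df = 2, p = 0.0002018
Dunn post-hoc (unadjusted two-tailed):
                        group1                       group2     z  p_value
1      outside_supplier_estate outside_supplier_smallgrower  4.12 3.79e-05
...
```

The same run is available as one command:

```r
library(palmwatch)
report <- run_pipeline(demo_config(out_dir = "results/demo", seed = 7))
```

or from the committed YAML config,
`run_pipeline(system.file("extdata", "demo.yaml", package = "palmwatch"))`.

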