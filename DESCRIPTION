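Package: palmwatch
Title: Satellite-Based Oil-Palm Plantation Efficiency Measurement and Panel Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures oil-palm plantation efficiency (the fraction of plantation
    area covered by palm canopy) from multispectral satellite imagery and analyses
    how it evolves around sustainability-certification events. Provides cloud-free
    annual compositing of repeated tile captures (provided cloud masks plus a
    pixel-wise multi-capture delta filter), bilinear up-sampling of 20 m / 60 m
    bands to a common 10 m grid, unsupervised k-means land-cover classification
    with frozen centroids, NDVI/NDMI/BSI spectral indices, polygon zonal
    statistics, random-intercept panel models with year indicators, and
    Kruskal-Wallis / Dunn group comparisons. A synthetic-scene and synthetic-panel
    generator with known ground truth makes the whole pipeline testable without
    satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
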