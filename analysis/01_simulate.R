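#!/usr/bin/env Rscript

# Stage 1 -- simulate the study inputs.
#
# Generates a seven-year series of multispectral tile captures over one
# synthetic plantation landscape with known land-cover ground truth, plus
# the plantation polygons. A gradual conversion of mature palm blocks to
# bare soil is injected from 2019 onward, so the downstream stages have a
# known efficiency decline to recover.

suppressMessages(library(palmwatch))

seed <- 7
years <- 2017:2023
out <- "results"
dir.create(file.path(out, "captures"), recursive = TRUE, showWarnings = FALSE)

spec <- scene_spec(width = 120, height = 120, cloud_fraction = 0.15, seed = seed)
series <- generate_scene_series(spec, years, annual_loss = 0.04)
plantations <- generate_plantations(spec, n = 12)
write_plantations_geojson(plantations, file.path(out, "plantations.geojson"))

# persist captures: one TIFF per native resolution group, plus the mask
res_groups <- split(names(S2_BAND_RES), S2_BAND_RES)
for (yr in names(series)) {
  sc <- series[[yr]]
  ydir <- file.path(out, "captures", yr)
  dir.create(ydir, showWarnings = FALSE)
  for (i in seq_along(sc$captures)) {
    cp <- sc$captures[[i]]
    for (res in names(res_groups)) {
      write_raster(cp$bands[res_groups[[res]]],
                   file.path(ydir, sprintf("capture%02d_%sm.tif", i, res)),
                   gt = cp$gt, crs = cp$crs)
    }
    write_raster(list(mask = cp$cloud_mask * 1),
                 file.path(ydir, sprintf("capture%02d_mask.tif", i)),
                 gt = cp$gt, crs = cp$crs)
  }
  # ground truth for later validation (integer class codes, CSV matrix)
  write.table(sc$truth_classes, file.path(ydir, "truth_classes.csv"),
              sep = ",", row.names = FALSE, col.names = FALSE)
}
jsonlite::write_json(
  list(seed = seed, years = years, n_captures = spec$n_captures,
       capture_dates_offset_days = 3, classes = SCENE_CLASSES),
  file.path(out, "simulation_meta.json"), auto_unbox = TRUE)

palm <- match("oil_palm_mature", SCENE_CLASSES)
shares <- vapply(series, function(s) mean(s$truth_classes == palm), 0)
cat("Simulated", length(years), "years x", spec$n_captures, "captures at",
    spec$width, "x", spec$height, "px\n")
cat("True mature-palm share by year:\n")
print(round(shares, 3))
cat("Plantations placed:", length(plantations), "\n")
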