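#' Write a multi-band raster as TIFF with a JSON georeferencing sidecar
#'
#' Pixel data go into a multi-slice 32-bit float TIFF. Nodata cells are
#' stored as 0 with a companion 0/1 validity slice per band (float TIFF
#' slices cannot carry NaN portably). The geotransform, CRS, band names
#' and nodata convention go into `<path>.json`. Requires the `tiff`
#' package.
#'
#' @param bands Named list of numeric matrices sharing one dimension.
#' @param path Output TIFF path.
#' @param gt A [geotransform()].
#' @param crs CRS label.
#' @return `path`, invisibly.
#' @export
write_raster <- function(bands, path, gt = geotransform(), crs = "EPSG:32650") {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for raster I/O")
  data <- lapply(bands, function(b) { b[is.na(b)] <- 0; b })
  masks <- lapply(bands, function(b) (!is.na(b)) * 1)
  tiff::writeTIFF(c(data, masks), path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(geotransform = unclass(gt), crs = crs, bands = names(bands),
               nodata = "mask-slices")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raster written by [write_raster()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must exist).
#' @return List: `bands` (named matrices, NaN restored to NA), `gt`, `crs`.
#' @export
read_raster <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for raster I/O")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  stk <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(stk)) stk <- list(stk)
  nb <- length(meta$bands)
  bands <- lapply(seq_len(nb), function(i) {
    b <- stk[[i]]
    b[stk[[nb + i]] < 0.5] <- NA_real_
    b
  })
  names(bands) <- meta$bands
  gt <- do.call(geotransform, as.list(meta$geotransform))
  list(bands = bands, gt = gt, crs = meta$crs)
}

#' Serialize a cluster model to JSON
#'
#' @param model A `cluster_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  obj <- list(k = model$k,
              centroids = as.data.frame(model$centroids),
              labels = model$labels,
              fit_metadata = model$fit_metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cluster model serialized by [write_cluster_model()]
#'
#' @param path JSON path.
#' @return A `cluster_model`.
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- as.matrix(obj$centroids)
  structure(list(k = obj$k, centroids = centroids,
                 labels = obj$labels, fit_metadata = obj$fit_metadata),
            class = "cluster_model")
}

#' Write plantation polygons as GeoJSON
#'
#' @param plantations List of plantation records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plantations_geojson <- function(plantations, path) {
  features <- lapply(plantations, function(p) {
    ring <- rbind(p$polygon, p$polygon[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(plantation_id = p$plantation_id, mill = p$mill,
                           type = p$type, cert_year = p$cert_year,
                           area_ha = p$area_ha),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read plantation polygons from GeoJSON
#'
#' @param path GeoJSON path (Polygon features with plantation attributes).
#' @return List of plantation records.
#' @export
read_plantations_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    colnames(ring) <- c("x", "y")
    pr <- f$properties
    list(plantation_id = pr$plantation_id, mill = pr$mill, type = pr$type,
         cert_year = pr$cert_year, polygon = ring, area_ha = pr$area_ha)
  })
}
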