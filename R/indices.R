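#' @keywords internal
# Elementwise normalized difference; a zero denominator yields nodata
# rather than a clamped value, since it only occurs on degenerate pixels.
normalized_difference <- function(num, den) {
  out <- num / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

index_grid <- function(name, values, composite) {
  if (!is.null(composite$valid_mask)) values[!composite$valid_mask] <- NA_real_
  structure(list(index_name = name, values = values, year = composite$year,
                 tile_id = composite$tile_id, gt = composite$gt),
            class = "index_grid")
}

require_bands <- function(composite, bands) {
  miss <- bands[!vapply(bands, function(b) !is.null(composite$bands[[b]]), TRUE)]
  if (length(miss)) stop("composite is missing band(s): ", paste(miss, collapse = ", "))
}

#' Normalized Difference Vegetation Index
#'
#' NDVI = (B08 - B04) / (B08 + B04). Healthy vegetation reflects strongly
#' in the near-infrared and absorbs red light, so higher values indicate
#' denser, healthier canopy.
#'
#' @param composite A [build_composite()] result (bands at 10 m).
#' @return An `index_grid` with values in \[-1, 1\] and nodata where the
#'   composite is invalid or the denominator vanishes.
#' @export
compute_ndvi <- function(composite) {
  require_bands(composite, c("B04", "B08"))
  v <- normalized_difference(composite$bands$B08 - composite$bands$B04,
                             composite$bands$B08 + composite$bands$B04)
  index_grid("NDVI", v, composite)
}

#' Normalized Difference Moisture Index
#'
#' NDMI = (B08 - B11) / (B08 + B11), contrasting near-infrared against
#' shortwave-infrared reflectance; sensitive to canopy and soil moisture.
#'
#' @inheritParams compute_ndvi
#' @return An `index_grid`.
#' @export
compute_ndmi <- function(composite) {
  require_bands(composite, c("B08", "B11"))
  v <- normalized_difference(composite$bands$B08 - composite$bands$B11,
                             composite$bands$B08 + composite$bands$B11)
  index_grid("NDMI", v, composite)
}

#' Bare Soil Index
#'
#' BSI = ((B11 + B04) - (B08 + B02)) / ((B11 + B04) + (B08 + B02)).
#' Highlights barren ground and non-vegetated surfaces; dense canopy gives
#' strongly negative values.
#'
#' @inheritParams compute_ndvi
#' @return An `index_grid`.
#' @export
compute_bsi <- function(composite) {
  require_bands(composite, c("B02", "B04", "B08", "B11"))
  a <- composite$bands$B11 + composite$bands$B04
  b <- composite$bands$B08 + composite$bands$B02
  index_grid("BSI", normalized_difference(a - b, a + b), composite)
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param px,py Point coordinates (vectors).
#' @param poly Two-column matrix of polygon vertices (ring; closure not
#'   required).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  vx <- poly[, 1]; vy <- poly[, 2]
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Internal: logical matrix of pixels whose centres fall inside the polygon.
polygon_pixel_mask <- function(gt, nrow, ncol, poly) {
  ctr <- pixel_centers(gt, nrow, ncol)
  px <- rep(ctr$x, each = nrow)
  py <- rep(ctr$y, times = ncol)
  matrix(point_in_polygon(px, py, poly), nrow, ncol)
}

#' Zonal mean of an index over a polygon
#'
#' Unweighted mean of index values at pixels whose centres fall inside the
#' polygon, excluding nodata.
#'
#' @param index An `index_grid` (or any list with `values` and `gt`).
#' @param polygon Two-column vertex matrix in map coordinates, or a
#'   plantation record carrying `$polygon`.
#' @return List with `mean` and `n` (count of contributing pixels).
#' @export
zonal_mean <- function(index, polygon) {
  if (is.list(polygon) && !is.null(polygon$polygon)) polygon <- polygon$polygon
  v <- index$values
  inside <- polygon_pixel_mask(index$gt, nrow(v), ncol(v), polygon)
  if (!any(inside)) stop("polygon covers no pixel centres of the grid")
  vals <- v[inside]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("zero valid pixels inside polygon")
  list(mean = mean(vals), n = length(vals))
}

#' Per-plantation-year index means
#'
#' Computes NDVI, NDMI and BSI on a composite and their zonal means for a
#' set of plantations.
#'
#' @param composite A composite.
#' @param plantations List of plantation records (see
#'   [generate_plantations()]).
#' @return data.frame with columns plantation_id, year, ndvi, ndmi, bsi,
#'   n_pixels.
#' @export
plantation_index_means <- function(composite, plantations) {
  grids <- list(ndvi = compute_ndvi(composite), ndmi = compute_ndmi(composite),
                bsi = compute_bsi(composite))
  rows <- lapply(plantations, function(p) {
    zs <- lapply(grids, zonal_mean, polygon = p$polygon)
    data.frame(plantation_id = p$plantation_id, year = composite$year,
               ndvi = zs$ndvi$mean, ndmi = zs$ndmi$mean, bsi = zs$bsi$mean,
               n_pixels = zs$ndvi$n)
  })
  do.call(rbind, rows)
}

#' Annual pooled index means
#'
#' One value per index and year, pooled over plantations. Both plantation-
#' weighted (mean of per-plantation means, the default) and pixel-weighted
#' aggregation are available.
#'
#' @param index_means data.frame from [plantation_index_means()] (possibly
#'   several years stacked).
#' @param weighting "plantation" or "pixel".
#' @return data.frame with columns year, ndvi, ndmi, bsi.
#' @export
annual_index_means <- function(index_means, weighting = c("plantation", "pixel")) {
  weighting <- match.arg(weighting)
  w <- if (weighting == "pixel") index_means$n_pixels else rep(1, nrow(index_means))
  agg <- function(col) {
    vapply(split(seq_len(nrow(index_means)), index_means$year), function(i)
      sum(index_means[[col]][i] * w[i]) / sum(w[i]), 0)
  }
  data.frame(year = as.integer(names(split(seq_len(nrow(index_means)), index_means$year))),
             ndvi = agg("ndvi"), ndmi = agg("ndmi"), bsi = agg("bsi"),
             row.names = NULL)
}
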