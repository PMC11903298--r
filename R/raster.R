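#' Band table for 13-band multispectral captures
#'
#' Named vector mapping band name to native ground resolution in metres.
#' Visible and NIR bands come at 10 m, red-edge/SWIR at 20 m and the
#' atmospheric bands at 60 m.
#'
#' @format Named numeric vector of length 13.
#' @export
S2_BAND_RES <- c(
  B01 = 60, B02 = 10, B03 = 10, B04 = 10,
  B05 = 20, B06 = 20, B07 = 20, B08 = 10, B8A = 20,
  B09 = 60, B10 = 60, B11 = 20, B12 = 20
)

#' Band names in canonical order
#' @format Character vector of length 13.
#' @export
S2_BANDS <- names(S2_BAND_RES)

#' North-up geotransform
#'
#' Registration convention used throughout the package: pixel grids are
#' row-major matrices; row 1 is the northernmost row; the centre of pixel
#' (r, c) sits at x = x0 + (c - 0.5) * pixel_size and
#' y = y0 - (r - 0.5) * pixel_size. All polygon tests use pixel centres.
#'
#' @param x0,y0 Map coordinates of the grid's north-west corner.
#' @param pixel_size Pixel edge length in metres (default 10).
#' @return A list of class `geotransform`.
#' @export
geotransform <- function(x0 = 0, y0 = 0, pixel_size = 10) {
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  structure(list(x0 = x0, y0 = y0, pixel_size = pixel_size),
            class = "geotransform")
}

#' Pixel-centre coordinates of a grid
#'
#' @param gt A [geotransform()].
#' @param nrow,ncol Grid dimensions.
#' @return List with numeric vectors `x` (length ncol) and `y` (length nrow).
#' @export
pixel_centers <- function(gt, nrow, ncol) {
  list(
    x = gt$x0 + (seq_len(ncol) - 0.5) * gt$pixel_size,
    y = gt$y0 - (seq_len(nrow) - 0.5) * gt$pixel_size
  )
}

#' Aggregate a 10 m grid to a coarser resolution by block mean
#'
#' Used by the scene generator to derive native 20 m / 60 m bands from the
#' 10 m ground truth. NA cells contaminate the whole block.
#'
#' @param grid Numeric matrix.
#' @param factor Integer block edge (2 or 6); must divide both dimensions.
#' @return Matrix of dimension `dim(grid) / factor`.
#' @export
block_aggregate <- function(grid, factor) {
  stopifnot(is.matrix(grid), factor >= 1, factor == round(factor))
  if (factor == 1) return(grid)
  nr <- nrow(grid); nc <- ncol(grid)
  if (nr %% factor != 0 || nc %% factor != 0)
    stop("grid dimensions must be divisible by the aggregation factor")
  ri <- (seq_len(nr) - 1) %/% factor + 1
  ci <- (seq_len(nc) - 1) %/% factor + 1
  # block means via two rowsum passes (rows, then transposed columns)
  m <- rowsum(grid, ri, reorder = TRUE)
  m <- t(rowsum(t(m), ci, reorder = TRUE)) / factor^2
  dimnames(m) <- NULL
  m
}

#' Up-sample a coarse band onto the 10 m grid with a linear kernel
#'
#' Bilinear interpolation at the target pixel centres, with edge clamping
#' (targets outside the outermost source centres take the boundary value,
#' so constants are preserved exactly). Any interpolation whose non-zero
#' weight stencil touches a nodata (NA) source cell yields nodata.
#'
#' @param grid Numeric matrix at 20 m or 60 m.
#' @param factor Integer resolution ratio to 10 m (2 or 6).
#' @return Matrix of dimension `dim(grid) * factor`.
#' @export
upsample_band <- function(grid, factor) {
  stopifnot(is.matrix(grid))
  if (length(grid) == 0) stop("empty grid")
  if (factor == 1) return(grid)
  if (!isTRUE(all.equal(factor, round(factor))) || factor < 1)
    stop("resolution ratio must be a positive integer")
  factor <- as.integer(factor)
  nr <- nrow(grid); nc <- ncol(grid)
  # fractional source index of each target pixel centre (pixel-centre registration)
  sidx <- function(n) {
    s <- (seq_len(n * factor) - 0.5) / factor + 0.5
    pmin(pmax(s, 1), n)
  }
  sr <- sidx(nr); sc <- sidx(nc)
  r0 <- pmin(floor(sr), nr - if (nr > 1) 1 else 0); r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(floor(sc), nc - if (nc > 1) 1 else 0); c1 <- pmin(c0 + 1, nc)
  wr <- sr - r0; wc <- sc - c0
  # outer products of the four corner weights
  w00 <- outer(1 - wr, 1 - wc); w01 <- outer(1 - wr, wc)
  w10 <- outer(wr, 1 - wc);     w11 <- outer(wr, wc)
  g00 <- grid[r0, c0, drop = FALSE]; g01 <- grid[r0, c1, drop = FALSE]
  g10 <- grid[r1, c0, drop = FALSE]; g11 <- grid[r1, c1, drop = FALSE]
  out <- w00 * g00 + w01 * g01 + w10 * g10 + w11 * g11
  # nodata contamination: cells entering with zero weight must not poison output
  na_touch <- (w00 > 0 & is.na(g00)) | (w01 > 0 & is.na(g01)) |
    (w10 > 0 & is.na(g10)) | (w11 > 0 & is.na(g11))
  zero_fix <- is.na(out) & !na_touch
  if (any(zero_fix)) {
    z <- function(w, g) { gg <- ifelse(w > 0, g, 0); gg[is.na(gg)] <- 0; w * gg }
    alt <- z(w00, g00) + z(w01, g01) + z(w10, g10) + z(w11, g11)
    out[zero_fix] <- alt[zero_fix]
  }
  out[na_touch] <- NA_real_
  out
}

#' Construct a tile capture
#'
#' One dated multispectral acquisition: 13 band grids at their native
#' resolutions plus a boolean cloud mask on the 10 m grid.
#'
#' @param tile_id MGRS-style tile identifier.
#' @param date Acquisition date (`Date` or coercible string).
#' @param bands Named list of numeric matrices covering all bands in
#'   [S2_BANDS]; each grid's dimension must equal the 10 m dimension divided
#'   by `native_resolution / 10`.
#' @param cloud_mask Logical matrix at 10 m (`TRUE` = cloudy).
#' @param gt A [geotransform()] of the 10 m grid.
#' @param crs CRS label carried as metadata (default UTM zone 50N).
#' @return Object of class `tile_capture`.
#' @export
tile_capture <- function(tile_id, date, bands, cloud_mask,
                         gt = geotransform(), crs = "EPSG:32650") {
  missing_b <- setdiff(S2_BANDS, names(bands))
  if (length(missing_b))
    stop("missing bands: ", paste(missing_b, collapse = ", "))
  dim10 <- dim(cloud_mask)
  if (is.null(dim10) || any(dim10 <= 0)) stop("cloud_mask must be a non-empty matrix")
  for (b in S2_BANDS) {
    f <- S2_BAND_RES[[b]] / 10
    if (!identical(dim(bands[[b]]), as.integer(dim10 / f)))
      stop("band ", b, " has inconsistent dimensions for its native resolution")
    v <- bands[[b]]
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
      stop("band ", b, " has reflectance outside [0, 1]")
  }
  structure(
    list(tile_id = tile_id, date = as.Date(date), bands = bands[S2_BANDS],
         cloud_mask = cloud_mask, gt = gt, crs = crs),
    class = "tile_capture"
  )
}

#' @export
print.tile_capture <- function(x, ...) {
  cat(sprintf("<tile_capture %s %s: %dx%d @ %gm, %.1f%% masked>\n",
              x$tile_id, format(x$date), nrow(x$cloud_mask), ncol(x$cloud_mask),
              x$gt$pixel_size, 100 * mean(x$cloud_mask)))
  invisible(x)
}

# Internal: all bands of a capture up-sampled onto the 10 m grid.
capture_bands_10m <- function(capture) {
  lapply(S2_BANDS, function(b) {
    upsample_band(capture$bands[[b]], S2_BAND_RES[[b]] / 10)
  }) |> setNames(S2_BANDS)
}
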