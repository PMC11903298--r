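#' Residual-cloud screening by multi-capture comparison (delta filter)
#'
#' Provided cloud masks are imperfect; residual clouds are caught by
#' comparing at least three near-simultaneous captures of the same tile
#' pixel by pixel. For each capture and pixel the deviation from the
#' per-pixel cross-capture median of the reference (visible) bands is
#' computed; a positive deviation exceeding `tau` in any reference band
#' flags the pixel as cloudy in that capture, since clouds brighten the
#' visible bands. The consensus median at each pixel is taken over the
#' captures not already flagged by their provided cloud masks, so a cloud
#' that the masks caught in one capture cannot drag the consensus towards
#' cloud brightness and get a clean capture flagged instead.
#'
#' Captures must already share the 10 m grid for the reference bands (B02
#' and B04 are native 10 m).
#'
#' @param captures List of at least three [tile_capture()]s of one tile.
#' @param tau Reflectance deviation threshold (default 0.12).
#' @param window Maximum allowed date span in days (default 15).
#' @param ref_bands Bands used for the comparison (default B02, B04).
#' @return List of logical matrices, one residual-cloud mask per capture.
#' @export
delta_cloud_filter <- function(captures, tau = 0.12, window = 15,
                               ref_bands = c("B02", "B04")) {
  if (length(captures) < 3)
    stop("delta filter needs at least 3 captures")
  tiles <- unique(vapply(captures, function(cp) cp$tile_id, ""))
  if (length(tiles) != 1) stop("captures must be of a single tile")
  dates <- as.Date(vapply(captures, function(cp) as.character(cp$date), ""))
  if (diff(range(dates)) > window)
    stop("capture date span ", diff(range(dates)), " d exceeds window ", window, " d")
  dims <- dim(captures[[1]]$bands[[ref_bands[1]]])
  flags <- lapply(captures, function(cp) matrix(FALSE, dims[1], dims[2]))
  for (b in ref_bands) {
    stack <- vapply(captures, function(cp) cp$bands[[b]], matrix(0, dims[1], dims[2]))
    consensus <- stack
    for (i in seq_along(captures)) {
      v <- consensus[, , i]
      v[captures[[i]]$cloud_mask] <- NA_real_
      consensus[, , i] <- v
    }
    med <- apply(consensus, c(1, 2), median, na.rm = TRUE)
    for (i in seq_along(captures)) {
      dev <- stack[, , i] - med
      flags[[i]] <- flags[[i]] | (!is.na(dev) & dev > tau)
    }
  }
  flags
}

#' Binary dilation of a cloud mask
#'
#' Grows the masked area by `r` pixels (square structuring element).
#' Partially clouded coarse-band cells contaminate neighbouring clean 10 m
#' pixels after up-sampling, so masks are dilated before merging.
#'
#' @param mask Logical matrix.
#' @param r Dilation radius in pixels.
#' @return Logical matrix.
#' @export
dilate_mask <- function(mask, r = 2L) {
  if (r <= 0) return(mask)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rd <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    cd <- max(1, 1 - dc):min(nc, nc - dc)
    out[rd, cd] <- out[rd, cd] | mask[rs, cs]
  }
  out
}

#' Merge captures into a cloud-free annual composite
#'
#' All bands are first up-sampled onto the shared 10 m grid, then merged
#' per pixel and band as the median of values from captures not flagged by
#' the union of the provided cloud mask and any extra (delta) mask.
#' Provenance counts the contributing captures per pixel; pixels never
#' observed cloud-free are nodata in every band.
#'
#' @param captures List of one or more [tile_capture()]s.
#' @param extra_masks Optional list of per-capture logical matrices (e.g.
#'   from [delta_cloud_filter()]) unioned with each capture's own mask.
#' @param year Calendar year recorded on the composite.
#' @param dilate Radius (pixels) by which the union mask is grown before
#'   merging, to exclude pixels whose coarse-band values are contaminated
#'   by sub-cell cloud; 0 disables.
#' @return Object of class `composite`: 13 bands at 10 m, `valid_mask`,
#'   `provenance`, geotransform and metadata.
#' @export
build_composite <- function(captures, extra_masks = NULL, year = NULL,
                            dilate = 0L) {
  if (length(captures) < 1) stop("no captures")
  gts <- unique(lapply(captures, function(cp) unclass(cp$gt)))
  if (length(gts) != 1) stop("captures have inconsistent geotransforms")
  dims <- dim(captures[[1]]$cloud_mask)
  if (is.null(extra_masks))
    extra_masks <- lapply(captures, function(cp) matrix(FALSE, dims[1], dims[2]))
  stopifnot(length(extra_masks) == length(captures))
  masks <- mapply(function(cp, em) dilate_mask(cp$cloud_mask | em, dilate),
                  captures, extra_masks, SIMPLIFY = FALSE)
  keep <- vapply(masks, function(m) !m, matrix(TRUE, dims[1], dims[2]))
  keep <- array(keep, c(dims, length(captures)))
  provenance <- apply(keep, c(1, 2), sum)
  bands10 <- lapply(captures, capture_bands_10m)
  out <- lapply(S2_BANDS, function(b) {
    stack <- array(unlist(lapply(bands10, `[[`, b)), c(dims, length(captures)))
    stack[!keep] <- NA_real_
    v <- apply(stack, c(1, 2), median, na.rm = TRUE)
    v[provenance == 0] <- NA_real_
    v
  })
  names(out) <- S2_BANDS
  if (is.null(year)) {
    year <- as.integer(format(captures[[1]]$date, "%Y"))
  }
  structure(
    list(tile_id = captures[[1]]$tile_id, year = year, bands = out,
         valid_mask = provenance > 0, provenance = provenance,
         gt = captures[[1]]$gt, crs = captures[[1]]$crs,
         meta = list(dates = vapply(captures, function(cp) format(cp$date), ""))),
    class = "composite"
  )
}

#' @export
print.composite <- function(x, ...) {
  cat(sprintf("<composite %s %s: %dx%d @ %gm, %.1f%% valid, %d captures>\n",
              x$tile_id, x$year, nrow(x$valid_mask), ncol(x$valid_mask),
              x$gt$pixel_size, 100 * mean(x$valid_mask), length(x$meta$dates)))
  invisible(x)
}

#' Compose one tile-year in one call
#'
#' Convenience wrapper running [delta_cloud_filter()] (when three or more
#' captures are available) followed by [build_composite()].
#'
#' @inheritParams delta_cloud_filter
#' @inheritParams build_composite
#' @return A `composite`.
#' @export
compose_annual <- function(captures, tau = 0.12, window = 15, year = NULL,
                           dilate = 3L) {
  extra <- if (length(captures) >= 3)
    delta_cloud_filter(captures, tau = tau, window = window) else NULL
  cmp <- build_composite(captures, extra_masks = extra, year = year,
                         dilate = dilate)
  cmp$meta$tau <- tau
  cmp
}
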