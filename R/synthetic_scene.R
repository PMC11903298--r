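#' Land-cover classes used by the scene generator
#' @format Character vector.
#' @export
SCENE_CLASSES <- c("oil_palm_mature", "oil_palm_immature", "other_vegetation",
                   "bare_soil", "water")

#' Default class spectra
#'
#' Per-class mean reflectance for all 13 bands plus a within-class noise
#' standard deviation. Values follow typical published reflectance ranges
#' for tropical vegetation, bare soil and open water; they are generator
#' configuration, not ground truth. Mature canopy is dark in the visible
#' and bright in the NIR; soil rises monotonically into the SWIR; water is
#' dark everywhere beyond the visible.
#'
#' @param noise_sd Within-class reflectance noise sd (default 0.012).
#' @return Named list per class: `mean` (13 bands) and `sd`.
#' @export
default_class_spectra <- function(noise_sd = 0.012) {
  m <- rbind(
    #                 B01    B02    B03    B04    B05   B06   B07   B08   B8A   B09   B10    B11   B12
    oil_palm_mature   = c(0.025, 0.022, 0.048, 0.030, 0.09, 0.30, 0.40, 0.48, 0.50, 0.12, 0.006, 0.13, 0.050),
    oil_palm_immature = c(0.050, 0.065, 0.110, 0.110, 0.17, 0.21, 0.24, 0.26, 0.28, 0.13, 0.006, 0.23, 0.130),
    other_vegetation  = c(0.035, 0.045, 0.090, 0.060, 0.13, 0.26, 0.31, 0.36, 0.38, 0.12, 0.006, 0.18, 0.090),
    bare_soil         = c(0.090, 0.110, 0.140, 0.180, 0.21, 0.24, 0.26, 0.28, 0.29, 0.15, 0.008, 0.38, 0.330),
    water             = c(0.060, 0.055, 0.045, 0.030, 0.02, 0.015, 0.012, 0.010, 0.010, 0.05, 0.004, 0.005, 0.004)
  )
  colnames(m) <- S2_BANDS
  lapply(setNames(rownames(m), rownames(m)),
         function(cl) list(mean = m[cl, ], sd = noise_sd))
}

# Bright, spectrally flat cumulus spectrum used to overwrite clouded pixels.
cloud_spectrum <- function() {
  s <- setNames(rep(0.70, 13), S2_BANDS)
  s[c("B10")] <- 0.30
  s[c("B11", "B12")] <- 0.45
  s
}

#' Scene specification
#'
#' Describes a synthetic multispectral scene with known per-pixel land-cover
#' ground truth. When `class_map` is not supplied, a coherent patch mosaic
#' is drawn from `class_mix` by seeded nearest-seed (Voronoi) tessellation.
#'
#' @param width,height Scene dimensions in 10 m pixels; must be divisible
#'   by 6 so that 20 m and 60 m native bands tile exactly.
#' @param pixel_size Pixel edge in metres (10).
#' @param class_mix Named proportions over [SCENE_CLASSES] used to draw the
#'   default class map. Defaults emulate a palm-dominated production
#'   landscape.
#' @param class_map Optional integer matrix of indices into [SCENE_CLASSES]
#'   overriding the generated mosaic.
#' @param class_spectra Per-class spectra, see [default_class_spectra()].
#' @param cloud_fraction Target fraction of pixels occluded per capture.
#' @param mask_miss_rate Fraction of truly cloudy pixels left out of the
#'   provided cloud mask, so the delta filter has residual clouds to catch.
#' @param n_captures Number of near-simultaneous captures (>= 3).
#' @param n_patches Number of tessellation seeds for the class mosaic.
#' @param seed Integer seed governing every random draw.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(width = 120, height = 120, pixel_size = 10,
                       class_mix = c(oil_palm_mature = 0.45,
                                     oil_palm_immature = 0.15,
                                     other_vegetation = 0.20,
                                     bare_soil = 0.15,
                                     water = 0.05),
                       class_map = NULL,
                       class_spectra = default_class_spectra(),
                       cloud_fraction = 0.25, mask_miss_rate = 0.10,
                       n_captures = 5, n_patches = 30, seed = 1) {
  if (width <= 0 || height <= 0) stop("scene dimensions must be positive")
  if (width %% 6 != 0 || height %% 6 != 0)
    stop("width and height must be divisible by 6 (60 m band tiling)")
  if (cloud_fraction < 0 || cloud_fraction > 1)
    stop("cloud_fraction must be in [0, 1]")
  stopifnot(all(names(class_mix) %in% SCENE_CLASSES),
            abs(sum(class_mix) - 1) < 1e-8,
            all(SCENE_CLASSES %in% names(class_spectra)),
            all(vapply(class_spectra, function(s) length(s$mean) == 13, TRUE)),
            n_captures >= 3)
  structure(list(width = width, height = height, pixel_size = pixel_size,
                 class_mix = class_mix, class_map = class_map,
                 class_spectra = class_spectra,
                 cloud_fraction = cloud_fraction,
                 mask_miss_rate = mask_miss_rate,
                 n_captures = n_captures, n_patches = n_patches, seed = seed),
            class = "scene_spec")
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Coherent class mosaic: nearest-seed tessellation with classes drawn from
# class_mix (expected proportions; patch areas vary). The tessellation is
# drawn on the 60 m block grid and expanded to 10 m, so land-cover patch
# edges align with the coarsest native band cells -- the block layout of
# managed plantation landscapes.
make_class_map <- function(width, height, class_mix, n_patches, block = 6L) {
  bw <- width %/% block; bh <- height %/% block
  sx <- runif(n_patches, 0.5, bw + 0.5)
  sy <- runif(n_patches, 0.5, bh + 0.5)
  scl <- sample(match(names(class_mix), SCENE_CLASSES), n_patches,
                replace = TRUE, prob = class_mix)
  px <- matrix(rep(seq_len(bw), each = bh), bh, bw)
  py <- matrix(rep(seq_len(bh), bw), bh, bw)
  best_d <- matrix(Inf, bh, bw)
  cls <- matrix(0L, bh, bw)
  for (i in seq_len(n_patches)) {
    d <- (px - sx[i])^2 + (py - sy[i])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    cls[upd] <- scl[i]
  }
  cls[rep(seq_len(bh), each = block), rep(seq_len(bw), each = block)]
}

# Soft-edged elliptical cloud field: returns opacity in [0,1] per pixel.
cloud_opacity_field <- function(width, height, cloud_fraction) {
  op <- matrix(0, height, width)
  if (cloud_fraction <= 0) return(op)
  target <- cloud_fraction * width * height
  guard <- 0
  while (sum(op > 0) < target && guard < 400) {
    guard <- guard + 1
    cx <- runif(1, 1, width); cy <- runif(1, 1, height)
    a <- runif(1, 4, 14); b <- runif(1, 4, 14)
    th <- runif(1, 0, pi)
    px <- matrix(rep(seq_len(width), each = height), height, width) - cx
    py <- matrix(rep(seq_len(height), width), height, width) - cy
    u <- (px * cos(th) + py * sin(th)) / a
    v <- (-px * sin(th) + py * cos(th)) / b
    d <- sqrt(u^2 + v^2)
    w <- pmin(pmax((1 - d) / 0.3, 0), 1) # opaque core, soft rim over d in [0.7, 1]
    op <- pmax(op, w)
  }
  op
}

#' Generate a synthetic multi-capture scene with ground truth
#'
#' Produces `n_captures` co-registered captures of one scene that differ
#' only in per-capture reflectance noise and in independently placed
#' soft-edged elliptical cloud patches (pixels blended towards a bright
#' cloud spectrum). Each capture carries a provided cloud mask that misses
#' a stated fraction of the truly cloudy pixels, so downstream delta
#' filtering has residual clouds to catch.
#'
#' @param spec A [scene_spec()].
#' @return List with elements:
#'   \describe{
#'     \item{captures}{list of [tile_capture()]s (dates 5 days apart);}
#'     \item{truth_classes}{integer matrix of indices into [SCENE_CLASSES];}
#'     \item{truth_bands}{noise-free clean reflectance, 13 bands at 10 m;}
#'     \item{cloud_truth}{list of logical matrices, the true occlusion
#'       footprint per capture (opacity > 0);}
#'     \item{gt}{the scene geotransform.}
#'   }
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    w <- spec$width; h <- spec$height
    cls <- spec$class_map
    if (is.null(cls)) cls <- make_class_map(w, h, spec$class_mix, spec$n_patches)
    stopifnot(identical(dim(cls), as.integer(c(h, w))))
    truth_bands <- lapply(setNames(S2_BANDS, S2_BANDS), function(b) {
      mu <- vapply(spec$class_spectra, function(s) s$mean[[b]], 0)
      matrix(mu[match(SCENE_CLASSES[cls], names(mu))], h, w)
    })
    csp <- cloud_spectrum()
    # twin-satellite constellation: joint revisit every ~3 days
    dates <- as.Date("2020-06-01") + 3 * (seq_len(spec$n_captures) - 1)
    cloud_truth <- list()
    captures <- vector("list", spec$n_captures)
    sd_by_class <- vapply(spec$class_spectra[SCENE_CLASSES], `[[`, 0, "sd")
    sd_map <- matrix(sd_by_class[cls], h, w)
    any_noise <- any(sd_by_class > 0)
    for (i in seq_len(spec$n_captures)) {
      op <- cloud_opacity_field(w, h, spec$cloud_fraction)
      cloudy <- op > 0
      cloud_truth[[i]] <- cloudy
      provided <- cloudy
      if (spec$mask_miss_rate > 0 && any(cloudy)) {
        idx <- which(cloudy)
        miss <- sample(idx, size = round(spec$mask_miss_rate * length(idx)))
        provided[miss] <- FALSE
      }
      bands10 <- lapply(S2_BANDS, function(b) {
        v <- truth_bands[[b]]
        cv <- matrix(csp[[b]], h, w)
        if (any_noise) {
          v <- v + matrix(rnorm(h * w), h, w) * sd_map
          cv <- cv + matrix(rnorm(h * w), h, w) * sd_map
        }
        v <- (1 - op) * v + op * cv
        pmin(pmax(v, 0), 1)
      })
      names(bands10) <- S2_BANDS
      native <- lapply(S2_BANDS, function(b)
        block_aggregate(bands10[[b]], S2_BAND_RES[[b]] / 10))
      names(native) <- S2_BANDS
      captures[[i]] <- tile_capture(
        tile_id = "50NNM", date = dates[i], bands = native,
        cloud_mask = provided, gt = geotransform(pixel_size = spec$pixel_size)
      )
    }
    list(captures = captures, truth_classes = cls, truth_bands = truth_bands,
         cloud_truth = cloud_truth, gt = geotransform(pixel_size = spec$pixel_size))
  })
}

#' Rectangular plantation polygons over a scene
#'
#' Places `n` non-overlapping axis-aligned rectangular plantations on the
#' scene's 10 m grid and returns them as polygon records in map
#' coordinates. Rectangle edges sit on pixel boundaries so the set of
#' covered pixel centres is unambiguous.
#'
#' @param spec A [scene_spec()] (for extent and geotransform).
#' @param n Number of plantations.
#' @param min_side,max_side Side lengths in pixels.
#' @param seed Integer seed.
#' @return List of plantation records: `plantation_id`, `mill`, `type`,
#'   `cert_year`, `polygon` (matrix of x,y vertices), `area_ha`.
#' @export
generate_plantations <- function(spec, n = 12, min_side = 8, max_side = 20,
                                 seed = spec$seed + 1) {
  gt <- geotransform(pixel_size = spec$pixel_size)
  types <- c("own_estate", "outside_supplier_estate", "outside_supplier_smallgrower")
  with_seed(seed, {
    placed <- list(); occ <- matrix(FALSE, spec$height, spec$width)
    guard <- 0
    while (length(placed) < n && guard < 2000) {
      guard <- guard + 1
      sw <- sample(min_side:max_side, 1); sh <- sample(min_side:max_side, 1)
      r0 <- sample(seq_len(spec$height - sh), 1)
      c0 <- sample(seq_len(spec$width - sw), 1)
      cells <- occ[r0:(r0 + sh - 1), c0:(c0 + sw - 1)]
      if (any(cells)) next
      occ[r0:(r0 + sh - 1), c0:(c0 + sw - 1)] <- TRUE
      # pixel-boundary rectangle in map coordinates
      x0 <- gt$x0 + (c0 - 1) * gt$pixel_size
      x1 <- gt$x0 + (c0 - 1 + sw) * gt$pixel_size
      y0 <- gt$y0 - (r0 - 1) * gt$pixel_size
      y1 <- gt$y0 - (r0 - 1 + sh) * gt$pixel_size
      poly <- cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
      k <- length(placed) + 1
      placed[[k]] <- list(
        plantation_id = sprintf("P%03d", k),
        mill = sprintf("M%02d", (k - 1) %% 6 + 1),
        type = types[(k - 1) %% 3 + 1],
        # first third certified early; offset from the type cycle so both
        # cohorts contain every plantation type
        cert_year = if (k <= ceiling(n / 3)) 2018 else 2023,
        polygon = poly,
        area_ha = sw * sh * (gt$pixel_size^2) / 1e4
      )
    }
    if (length(placed) < n) stop("could not place ", n, " non-overlapping plantations")
    placed
  })
}

#' Multi-year scene series with a declining palm footprint
#'
#' Re-generates the same landscape for several years while converting a
#' cumulative fraction of the initial mature-palm area (in whole 60 m
#' management blocks, preserving the block-aligned layout) to bare soil
#' each year, emulating a gradual efficiency decline whose magnitude is
#' known exactly from the ground truth.
#'
#' @param spec Base [scene_spec()] (defines year-1 truth).
#' @param years Integer vector of calendar years.
#' @param annual_loss Fraction of the original mature-palm pixels converted
#'   to bare soil per elapsed year (default 0.04).
#' @return Named list (by year) of [generate_scene()] results.
#' @export
generate_scene_series <- function(spec, years, annual_loss = 0.04) {
  stopifnot(length(years) >= 1, annual_loss >= 0)
  base <- generate_scene(spec)
  cls0 <- base$truth_classes
  palm <- match("oil_palm_mature", SCENE_CLASSES)
  soil <- match("bare_soil", SCENE_CLASSES)
  # 60 m blocks that are mature palm (the map is block-constant)
  block <- 6L
  bh <- nrow(cls0) %/% block; bw <- ncol(cls0) %/% block
  bcls <- cls0[seq(1, nrow(cls0), by = block), seq(1, ncol(cls0), by = block)]
  palm_blocks <- which(bcls == palm)
  order_blk <- with_seed(spec$seed + 99, sample(palm_blocks))
  out <- list()
  for (i in seq_along(years)) {
    bc <- bcls
    n_lost <- min(length(order_blk),
                  round(annual_loss * (i - 1) * length(palm_blocks)))
    if (n_lost > 0) bc[order_blk[seq_len(n_lost)]] <- soil
    cls <- bc[rep(seq_len(bh), each = block), rep(seq_len(bw), each = block)]
    sp <- spec
    sp$class_map <- cls
    sp$seed <- spec$seed + i
    out[[as.character(years[i])]] <- generate_scene(sp)
  }
  out
}
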