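# Independent brute-force oracles used by the tests. These deliberately do
# not reuse any code path they are checking.

# Bilinear interpolation evaluated pointwise with explicit loops.
oracle_bilinear <- function(grid, factor) {
  nr <- nrow(grid); nc <- ncol(grid)
  out <- matrix(NA_real_, nr * factor, nc * factor)
  for (R in seq_len(nr * factor)) {
    for (C in seq_len(nc * factor)) {
      sr <- min(max((R - 0.5) / factor + 0.5, 1), nr)
      sc <- min(max((C - 0.5) / factor + 0.5, 1), nc)
      r0 <- min(floor(sr), nr - (nr > 1)); r1 <- min(r0 + 1, nr)
      c0 <- min(floor(sc), nc - (nc > 1)); c1 <- min(c0 + 1, nc)
      wr <- sr - r0; wc <- sc - c0
      acc <- 0; bad <- FALSE
      for (p in list(c(r0, c0, (1 - wr) * (1 - wc)), c(r0, c1, (1 - wr) * wc),
                     c(r1, c0, wr * (1 - wc)), c(r1, c1, wr * wc))) {
        if (p[3] > 0) {
          v <- grid[p[1], p[2]]
          if (is.na(v)) bad <- TRUE else acc <- acc + p[3] * v
        }
      }
      out[R, C] <- if (bad) NA_real_ else acc
    }
  }
  out
}

# Mean of grid values whose pixel centres fall in an axis-aligned rectangle,
# using direct coordinate comparisons (independent of ray casting).
oracle_rect_zonal <- function(values, gt, xmin, xmax, ymin, ymax) {
  acc <- c(); n <- 0
  for (r in seq_len(nrow(values))) {
    for (cc in seq_len(ncol(values))) {
      x <- gt$x0 + (cc - 0.5) * gt$pixel_size
      y <- gt$y0 - (r - 0.5) * gt$pixel_size
      if (x > xmin && x < xmax && y > ymin && y < ymax && !is.na(values[r, cc])) {
        acc <- c(acc, values[r, cc]); n <- n + 1
      }
    }
  }
  list(mean = mean(acc), n = n)
}

# Per-pixel nearest-centroid classification by explicit loops.
oracle_nearest <- function(x, centroids) {
  out <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    d <- rep(Inf, nrow(centroids))
    for (j in seq_len(nrow(centroids)))
      d[j] <- sum((x[i, ] - centroids[j, ])^2)
    out[i] <- which(d == min(d))[1]
  }
  out
}

# Kruskal-Wallis H from the rank-sum definition with tie correction.
oracle_kw_h <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Dunn pairwise z from the textbook formula.
oracle_dunn_z <- function(values, groups, g1, g2) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  (mr[[g1]] - mr[[g2]]) /
    sqrt((N * (N + 1) / 12 - tie_term) * (1 / ng[[g1]] + 1 / ng[[g2]]))
}

# Wilcoxon rank-sum chi-squared form (normal approximation squared, tie
# corrected, no continuity correction) for the two-group equivalence check.
oracle_wilcoxon_chisq <- function(x, y) {
  v <- c(x, y)
  r <- rank(v)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (N + 1) / 2
  ties <- table(v)
  VW <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  (W - EW)^2 / VW
}

# Exhaustive minimiser of the 2-cluster within-group sum of squares over all
# 2-partitions of <= 12 points.
oracle_best_2partition <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (!any(grp) || all(grp)) next
    ss <- 0
    for (g in list(x[grp, , drop = FALSE], x[!grp, , drop = FALSE])) {
      mu <- colMeans(g)
      ss <- ss + sum(sweep(g, 2, mu)^2)
    }
    if (ss < best) best <- ss
  }
  best
}

# Small labeled composite built directly from band matrices (bypasses the
# scene generator) for index and classification tests.
make_composite <- function(bands, gt = geotransform(), year = 2020,
                           valid = NULL) {
  dims <- dim(bands[[1]])
  if (is.null(valid)) valid <- matrix(TRUE, dims[1], dims[2])
  structure(list(tile_id = "TEST", year = year, bands = bands,
                 valid_mask = valid, provenance = valid * 1L,
                 gt = gt, crs = "EPSG:32650", meta = list()),
            class = "composite")
}

# Full 13-band constant composite with selected bands overridden.
make_composite13 <- function(nr, nc, override = list(), fill = 0.2, ...) {
  bands <- lapply(setNames(S2_BANDS, S2_BANDS),
                  function(b) matrix(fill, nr, nc))
  for (b in names(override)) bands[[b]] <- override[[b]]
  make_composite(bands, ...)
}
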