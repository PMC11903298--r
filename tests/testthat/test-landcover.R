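two_clouds <- function(n_per = 6, gap = 1, sd = 0.02, seed = 3) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(n_per * 13, 0.2, sd), n_per, 13)
    b <- matrix(rnorm(n_per * 13, 0.2 + gap / sqrt(13), sd), n_per, 13)
    colnames(a) <- colnames(b) <- S2_BANDS
    rbind(a, b)
  })
}

test_that("k = 1 reduces to the sample mean and k-means is seed-deterministic", {
  x <- two_clouds()
  m1 <- fit_kmeans(x, k = 1, seed = 5)
  expect_equal(as.numeric(m1$centroids), as.numeric(colMeans(x)))
  ma <- fit_kmeans(x, k = 2, seed = 7)
  mb <- fit_kmeans(x, k = 2, seed = 7)
  expect_identical(ma$centroids, mb$centroids)
})

test_that("two separated clouds are recovered and match the exhaustive 2-partition", {
  x <- two_clouds(n_per = 6, gap = 1, sd = 0.02)
  m <- fit_kmeans(x, k = 2, seed = 1)
  mu_a <- colMeans(x[1:6, ]); mu_b <- colMeans(x[7:12, ])
  d <- function(c1, c2) sqrt(sum((c1 - c2)^2))
  # each centroid sits within noise of one cloud mean
  match_err <- min(d(m$centroids[1, ], mu_a) + d(m$centroids[2, ], mu_b),
                   d(m$centroids[1, ], mu_b) + d(m$centroids[2, ], mu_a))
  expect_lt(match_err, 0.1)
  expect_equal(m$fit_metadata$inertia, oracle_best_2partition(x),
               tolerance = 1e-8)
})

test_that("k-means rejects invalid inputs", {
  x <- two_clouds()
  expect_error(fit_kmeans(x, k = 0), "at least 1")
  expect_error(fit_kmeans(x[1:3, ], k = 5), "sample size below k")
  same <- matrix(0.3, 10, 13, dimnames = list(NULL, S2_BANDS))
  expect_error(fit_kmeans(same, k = 2), "degenerate")
  x[2, 4] <- NA
  expect_error(fit_kmeans(x, k = 2), "missing values")
})

test_that("cluster labeling enforces a complete, known-class map", {
  m <- fit_kmeans(two_clouds(), k = 2, seed = 1)
  lab <- label_clusters(m, c("oil_palm_mature", "other"))
  expect_identical(lab$labels, c("oil_palm_mature", "other"))
  expect_error(label_clusters(m, c("oil_palm_mature")), "every cluster")
  expect_error(label_clusters(m, setNames(c("other", "other"), c("1", "3"))),
               "every cluster")
  expect_error(label_clusters(m, c("oil_palm_mature", "swamp")), "unknown class")
})

test_that("majority-truth labeling reproduces class proportions within 5 points", {
  sp <- scene_spec(width = 60, height = 60, cloud_fraction = 0.1, seed = 8)
  sc <- generate_scene(sp)
  cmp <- compose_annual(sc$captures, year = 2020)
  px <- sample_pixels(cmp, 1e5, seed = 1)
  m <- fit_kmeans(px, k = 8, seed = 1)
  idx <- which(cmp$valid_mask)
  x <- matrix(vapply(S2_BANDS, function(b) cmp$bands[[b]][idx],
                     numeric(length(idx))), ncol = 13)
  m <- label_clusters_by_truth(m, x, sc$truth_classes[idx])
  cg <- classify_composite(cmp, m)
  to_cover <- c("oil_palm_mature", "oil_palm_immature", "other_vegetation",
                "other", "other")
  for (cc in COVER_CLASSES) {
    truth_frac <- mean(to_cover[sc$truth_classes[idx]] == cc)
    pred_frac <- mean(m$labels[cg$classes[idx]] == cc)
    expect_lt(abs(truth_frac - pred_frac), 0.05)
  }
})

test_that("classification is frozen, tie-stable, and matches the brute-force loop", {
  centroids <- matrix(c(rep(0.2, 13), rep(0.6, 13), rep(0.9, 13)), 3,
                      byrow = TRUE, dimnames = list(NULL, S2_BANDS))
  m <- structure(list(k = 3, centroids = centroids,
                      labels = c("oil_palm_mature", "other_vegetation", "other"),
                      fit_metadata = list()), class = "cluster_model")
  # pixel exactly at a centroid
  cmp1 <- make_composite13(1, 1, fill = 0.6)
  expect_equal(classify_composite(cmp1, m)$classes[1, 1], 2L)
  # pixel equidistant from centroids 1 and 2 -> lowest index
  cmp2 <- make_composite13(1, 1, fill = 0.4)
  expect_equal(classify_composite(cmp2, m)$classes[1, 1], 1L)
  # full random grid vs brute force
  set.seed(4)
  nr <- 10; nc <- 10
  bands <- lapply(setNames(S2_BANDS, S2_BANDS),
                  function(b) matrix(runif(nr * nc), nr, nc))
  cmp3 <- make_composite(bands)
  got <- classify_composite(cmp3, m)$classes
  x <- vapply(S2_BANDS, function(b) as.vector(bands[[b]]), numeric(nr * nc))
  expect_equal(as.vector(got), oracle_nearest(x, centroids))
  # repeated application is bitwise identical (pure function)
  expect_identical(classify_composite(cmp3, m)$classes, got)
  # unlabeled model refused
  m$labels <- NULL
  expect_error(classify_composite(cmp3, m), "unlabeled")
})

test_that("nodata pixels stay unclassified", {
  centroids <- matrix(rep(c(0.2, 0.8), each = 13), 2, byrow = TRUE)
  m <- structure(list(k = 2, centroids = centroids,
                      labels = c("oil_palm_mature", "other"),
                      fit_metadata = list()), class = "cluster_model")
  valid <- matrix(TRUE, 2, 2); valid[1, 2] <- FALSE
  cmp <- make_composite13(2, 2, fill = 0.21, valid = valid)
  cg <- classify_composite(cmp, m)
  expect_true(is.na(cg$classes[1, 2]))
  expect_equal(sum(!is.na(cg$classes)), 3)
})

test_that("coverage extraction counts classes at pixel centres", {
  classes <- matrix(1L, 10, 10)
  classes[6:10, ] <- 4L # bottom half "other"
  cg <- structure(list(classes = classes,
                       class_names = c("oil_palm_mature", "oil_palm_immature",
                                       "other_vegetation", "other"),
                       gt = geotransform(), year = 2020), class = "class_grid")
  full <- list(plantation_id = "P1",
               polygon = cbind(x = c(0, 100, 100, 0), y = c(0, 0, -50, -50)))
  expect_equal(extract_coverage(cg, full)$coverage, 1.0)
  half <- list(plantation_id = "P2",
               polygon = cbind(x = c(0, 100, 100, 0), y = c(0, 0, -100, -100)))
  cr <- extract_coverage(cg, half)
  expect_equal(cr$coverage, 0.5)
  expect_equal(cr$valid_pixel_count, 100)
  expect_equal(sum(cr$class_pixel_counts), cr$valid_pixel_count)
  # mature-only mode counts the same here (no immature present)
  expect_equal(extract_coverage(cg, half, mode = "mature_only")$coverage, 0.5)
  # mixed mature/immature polygon distinguishes the modes
  classes[1:5, ] <- 2L
  cg$classes <- classes
  expect_equal(extract_coverage(cg, half)$coverage, 0.5)
  expect_equal(extract_coverage(cg, half, mode = "mature_only")$coverage, 0)
  # all-nodata polygon errors
  cg$classes[] <- NA_integer_
  expect_error(extract_coverage(cg, half), "zero valid pixels")
})

test_that("perfect classification reproduces ground-truth coverage exactly", {
  # class grid constructed directly from the ground truth: coverage must
  # equal the true palm fraction at the same pixel centres, bit for bit
  sp <- scene_spec(width = 36, height = 36, cloud_fraction = 0, seed = 2)
  sc <- generate_scene(sp)
  to_cover <- c(1L, 2L, 3L, 4L, 4L) # scene classes onto cover classes
  cg <- structure(list(classes = matrix(to_cover[sc$truth_classes], 36, 36),
                       class_names = COVER_CLASSES,
                       gt = sc$gt, year = 2020), class = "class_grid")
  pl <- generate_plantations(sp, n = 5, min_side = 5, max_side = 10)
  for (p in pl) {
    expect_identical(extract_coverage(cg, p)$coverage,
                     truth_coverage(sc$truth_classes, sc$gt, p))
    expect_identical(extract_coverage(cg, p, mode = "mature_only")$coverage,
                     truth_coverage(sc$truth_classes, sc$gt, p,
                                    mode = "mature_only"))
  }
})

test_that("measured coverage decreases monotonically with the true palm share", {
  spectra <- default_class_spectra(noise_sd = 0.01)
  centroids <- t(vapply(SCENE_CLASSES, function(cl) spectra[[cl]]$mean,
                        numeric(13)))
  m <- structure(list(k = 5, centroids = centroids,
                      labels = c("oil_palm_mature", "oil_palm_immature",
                                 "other_vegetation", "other", "other"),
                      fit_metadata = list()), class = "cluster_model")
  # explicit block-aligned maps with exact palm shares (6x6 blocks of 6 px)
  n_palm_blocks <- c(24, 18, 12, 8, 4)
  poly <- list(plantation_id = "ALL",
               polygon = cbind(x = c(0, 360, 360, 0), y = c(0, 0, -360, -360)))
  got <- vapply(n_palm_blocks, function(nb) {
    bcls <- rep(match("bare_soil", SCENE_CLASSES), 36)
    bcls[seq_len(nb)] <- match("oil_palm_mature", SCENE_CLASSES)
    cls <- matrix(bcls, 6, 6)[rep(1:6, each = 6), rep(1:6, each = 6)]
    sp <- scene_spec(width = 36, height = 36, class_map = cls,
                     cloud_fraction = 0.1, seed = 21,
                     class_spectra = spectra)
    sc <- generate_scene(sp)
    cmp <- compose_annual(sc$captures, year = 2020)
    extract_coverage(classify_composite(cmp, m), poly)$coverage
  }, 0)
  expect_true(all(diff(got) < 0))
})
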