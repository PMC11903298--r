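#' Land-cover labels assignable to clusters
#' @format Character vector.
#' @export
COVER_CLASSES <- c("oil_palm_mature", "oil_palm_immature", "other_vegetation", "other")

#' Draw a pixel sample from a composite for model fitting
#'
#' Uniform random subsample of valid pixels, as 13-band reflectance
#' vectors.
#'
#' @param composite A composite.
#' @param n Maximum sample size (default 100000).
#' @param seed Integer seed.
#' @return Numeric matrix, one row per pixel, 13 columns.
#' @export
sample_pixels <- function(composite, n = 1e5, seed = 42) {
  valid <- which(composite$valid_mask)
  if (length(valid) == 0) stop("composite has no valid pixels")
  idx <- if (length(valid) > n)
    with_seed(seed, sample(valid, n)) else valid
  m <- vapply(S2_BANDS, function(b) composite$bands[[b]][idx], numeric(length(idx)))
  m <- matrix(m, ncol = 13, dimnames = list(NULL, S2_BANDS))
  m[stats::complete.cases(m), , drop = FALSE]
}

# k-means++ seeding: first centre uniform, each subsequent centre sampled
# with probability proportional to squared distance from the chosen set.
# Deterministic given the RNG state of the caller.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- colSums((t(x) - centers[1, ])^2)
  if (k > 1) for (j in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    nxt <- sample.int(n, 1, prob = p)
    centers[j, ] <- x[nxt, ]
    d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
  }
  centers
}

#' Fit an unlabeled k-means cluster model in band space
#'
#' Lloyd iterations to convergence from seeded k-means++ initializations
#' (`n_init` restarts; lowest within-cluster inertia kept), so the fit is
#' deterministic given the seed. Features are raw reflectances of all 13
#' bands, unstandardized. The fitted centroids are meant to be frozen and
#' reapplied to every tile-year composite.
#'
#' @param pixels Matrix of band vectors (rows = pixels, 13 columns), e.g.
#'   from [sample_pixels()]; must contain no missing values.
#' @param k Number of clusters (>= 1; default 8; k = 1 reduces to the
#'   sample mean).
#' @param seed Integer seed.
#' @param n_init Number of k-means++ restarts (default 10).
#' @param iter_max Maximum Lloyd iterations per restart.
#' @return Object of class `cluster_model` with `k`, `centroids`, `labels`
#'   (NULL until [label_clusters()]) and `fit_metadata`.
#' @export
fit_kmeans <- function(pixels, k = 8, seed = 42, n_init = 10, iter_max = 100) {
  stopifnot(is.matrix(pixels))
  if (k < 1) stop("k must be at least 1")
  if (anyNA(pixels)) stop("pixel sample contains missing values")
  if (nrow(pixels) < k) stop("sample size below k")
  if (k == 1) {
    ctr <- matrix(colMeans(pixels), 1, dimnames = list(NULL, colnames(pixels)))
    return(structure(
      list(k = 1L, centroids = ctr, labels = NULL,
           fit_metadata = list(sample_size = nrow(pixels), seed = seed,
                               inertia = sum(sweep(pixels, 2, ctr[1, ])^2),
                               iterations = 0L)),
      class = "cluster_model"))
  }
  if (nrow(unique(pixels)) < k)
    stop("degenerate sample: fewer than k distinct points")
  km <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      init <- kmeanspp_init(pixels, k)
      fit <- tryCatch(
        suppressWarnings(kmeans(pixels, centers = init, iter.max = iter_max,
                                algorithm = "Lloyd")),
        error = function(e) lloyd_reseed(pixels, init, iter_max)
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
  centroids <- km$centers
  colnames(centroids) <- colnames(pixels)
  structure(
    list(k = k, centroids = centroids, labels = NULL,
         fit_metadata = list(sample_size = nrow(pixels), seed = seed,
                             inertia = km$tot.withinss,
                             iterations = km$iter)),
    class = "cluster_model"
  )
}

#' Attach land-cover labels to a fitted cluster model
#'
#' The by-hand classification step of the workflow, externalized as
#' configuration: every cluster index must be mapped to one of
#' [COVER_CLASSES].
#'
#' @param model An unlabeled `cluster_model`.
#' @param labeling Character vector of class names, either named by cluster
#'   index ("1".."k") or positional of length k.
#' @return The labeled model.
#' @export
label_clusters <- function(model, labeling) {
  stopifnot(inherits(model, "cluster_model"))
  if (!is.null(names(labeling))) {
    idx <- suppressWarnings(as.integer(names(labeling)))
    if (anyNA(idx) || !setequal(idx, seq_len(model$k)))
      stop("labeling must cover every cluster index 1..k exactly once")
    labeling <- labeling[order(idx)]
  } else if (length(labeling) != model$k) {
    stop("labeling must cover every cluster index 1..k exactly once")
  }
  bad <- setdiff(unique(labeling), COVER_CLASSES)
  if (length(bad)) stop("unknown class name(s): ", paste(bad, collapse = ", "))
  model$labels <- unname(labeling)
  model$fit_metadata$labeling <- model$labels
  model
}

#' Label clusters by majority ground truth (synthetic scenes)
#'
#' Assigns each cluster the scene class most frequent among its member
#' pixels, mapped onto [COVER_CLASSES] (bare soil and water become
#' "other"). Stands in for the by-hand screening step when ground truth is
#' available.
#'
#' @param model Unlabeled `cluster_model`.
#' @param pixels The band-vector matrix the truth refers to.
#' @param truth Integer vector of [SCENE_CLASSES] indices, one per pixel row.
#' @return Labeled model.
#' @export
label_clusters_by_truth <- function(model, pixels, truth) {
  assign <- nearest_centroid(pixels, model$centroids)
  to_cover <- c(oil_palm_mature = "oil_palm_mature",
                oil_palm_immature = "oil_palm_immature",
                other_vegetation = "other_vegetation",
                bare_soil = "other", water = "other")
  lab <- vapply(seq_len(model$k), function(j) {
    members <- truth[assign == j]
    if (length(members) == 0) return("other")
    to_cover[[SCENE_CLASSES[as.integer(names(which.max(table(members))))]]]
  }, "")
  label_clusters(model, lab)
}

# Lloyd iterations with deterministic empty-cluster handling: an emptied
# cluster is re-seeded from the point farthest from its assigned centre.
lloyd_reseed <- function(x, centers, iter_max) {
  k <- nrow(centers)
  for (it in seq_len(iter_max)) {
    assign <- nearest_centroid(x, centers)
    new_c <- centers
    for (j in seq_len(k)) {
      mem <- assign == j
      if (any(mem)) {
        new_c[j, ] <- colMeans(x[mem, , drop = FALSE])
      } else {
        d2 <- rowSums((x - centers[assign, , drop = FALSE])^2)
        far <- which.max(d2)
        new_c[j, ] <- x[far, ]
        assign[far] <- j
      }
    }
    done <- max(rowSums((new_c - centers)^2)) < 1e-16
    centers <- new_c
    if (done) break
  }
  assign <- nearest_centroid(x, centers)
  tot <- sum(rowSums((x - centers[assign, , drop = FALSE])^2))
  list(centers = centers, cluster = assign, tot.withinss = tot, iter = it)
}

# Nearest centroid (Euclidean). Ties -- including floating-point near-ties
# from the expanded distance formula -- break to the lowest cluster index.
nearest_centroid <- function(x, centroids) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centroids))) -
    2 * x %*% t(centroids) +
    outer(rep(1, nrow(x)), rowSums(centroids^2))
  dmin <- do.call(pmin, lapply(seq_len(ncol(d2)), function(j) d2[, j]))
  max.col(d2 <= dmin + 1e-12, ties.method = "first")
}

#' Classify a composite with frozen centroids
#'
#' Each valid pixel is assigned the land-cover class of its nearest
#' centroid in 13-band space (Euclidean distance; ties broken towards the
#' lowest cluster index). No centroid update occurs, so classifications
#' are comparable across years.
#'
#' @param composite A composite.
#' @param model A labeled `cluster_model`.
#' @return List of class `class_grid`: `classes` (integer matrix of cluster
#'   indices, NA = nodata), `class_names` (per-cluster label), `gt`, `year`.
#' @export
classify_composite <- function(composite, model) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(model$labels)) stop("cluster model is unlabeled; call label_clusters()")
  dims <- dim(composite$valid_mask)
  valid <- which(composite$valid_mask)
  x <- vapply(S2_BANDS, function(b) composite$bands[[b]][valid], numeric(length(valid)))
  x <- matrix(x, ncol = 13)
  cl <- matrix(NA_integer_, dims[1], dims[2])
  ok <- stats::complete.cases(x)
  cl[valid[ok]] <- nearest_centroid(x[ok, , drop = FALSE], model$centroids)
  structure(list(classes = cl, class_names = model$labels,
                 gt = composite$gt, year = composite$year,
                 tile_id = composite$tile_id),
            class = "class_grid")
}

#' Oil-palm coverage of a plantation polygon
#'
#' Counts classified pixels at centres inside the polygon and reports the
#' fraction covered by oil palm. Following the published coverage figures,
#' both mature and immature palm count by default; a mature-only mode is
#' available.
#'
#' @param class_grid A [classify_composite()] result.
#' @param plantation Plantation record with `$polygon` and
#'   `$plantation_id`.
#' @param year Calendar year stamped on the record (defaults to the grid's).
#' @param mode "mature_plus_immature" (default) or "mature_only".
#' @return List of class `coverage_record`: plantation_id, year, coverage,
#'   valid_pixel_count, class_pixel_counts.
#' @export
extract_coverage <- function(class_grid, plantation, year = class_grid$year,
                             mode = c("mature_plus_immature", "mature_only")) {
  mode <- match.arg(mode)
  cl <- class_grid$classes
  inside <- polygon_pixel_mask(class_grid$gt, nrow(cl), ncol(cl),
                               plantation$polygon)
  vals <- cl[inside]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("zero valid pixels inside polygon")
  per_class <- vapply(COVER_CLASSES, function(cc)
    sum(class_grid$class_names[vals] == cc), 0L)
  palm_classes <- if (mode == "mature_only") "oil_palm_mature"
    else c("oil_palm_mature", "oil_palm_immature")
  structure(
    list(plantation_id = plantation$plantation_id, year = year,
         coverage = sum(per_class[palm_classes]) / length(vals),
         valid_pixel_count = length(vals),
         class_pixel_counts = per_class, mode = mode),
    class = "coverage_record"
  )
}

#' Coverage table for many plantations
#'
#' @param class_grid A `class_grid`.
#' @param plantations List of plantation records.
#' @inheritParams extract_coverage
#' @return data.frame: plantation_id, year, coverage, valid_pixel_count.
#' @export
coverage_table <- function(class_grid, plantations,
                           mode = c("mature_plus_immature", "mature_only")) {
  mode <- match.arg(mode)
  rows <- lapply(plantations, function(p) {
    cr <- extract_coverage(class_grid, p, mode = mode)
    data.frame(plantation_id = cr$plantation_id, year = cr$year,
               coverage = cr$coverage, valid_pixel_count = cr$valid_pixel_count)
  })
  do.call(rbind, rows)
}

#' Ground-truth palm fraction inside a polygon
#'
#' Reference quantity for recovery checks: the fraction of pixel centres
#' inside the polygon whose ground-truth class is oil palm.
#'
#' @param truth_classes Integer matrix of [SCENE_CLASSES] indices.
#' @param gt Scene [geotransform()].
#' @param plantation Plantation record.
#' @param mode Coverage mode as in [extract_coverage()].
#' @param valid_mask Optional logical matrix restricting the comparison to
#'   the pixels the pipeline could observe (the composite's valid mask),
#'   so measured and true coverage share one denominator.
#' @return Fraction in \[0, 1\].
#' @export
truth_coverage <- function(truth_classes, gt, plantation,
                           mode = c("mature_plus_immature", "mature_only"),
                           valid_mask = NULL) {
  mode <- match.arg(mode)
  inside <- polygon_pixel_mask(gt, nrow(truth_classes), ncol(truth_classes),
                               plantation$polygon)
  if (!is.null(valid_mask)) inside <- inside & valid_mask
  vals <- truth_classes[inside]
  palm <- match("oil_palm_mature", SCENE_CLASSES)
  if (mode == "mature_plus_immature")
    palm <- c(palm, match("oil_palm_immature", SCENE_CLASSES))
  mean(vals %in% palm)
}
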