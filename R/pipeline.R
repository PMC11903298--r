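#' Default demonstration configuration
#'
#' A synthetic end-to-end run: one tile, 2017-2023, 12 plantations, a
#' generator-injected gradual palm decline, k = 8 clusters, coverage as
#' mature plus immature palm.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed; every random draw in the run flows from it.
#' @return A config list (as produced by parsing the YAML config).
#' @export
demo_config <- function(out_dir = tempfile("palmwatch_run_"), seed = 7) {
  list(
    seed = seed,
    out_dir = out_dir,
    scene = list(width = 120, height = 120, cloud_fraction = 0.15,
                 n_captures = 3, annual_loss = 0.04),
    years = 2017:2023,
    n_plantations = 12,
    compositing = list(tau = 0.12, window = 15),
    kmeans = list(k = 8, sample_size = 8000),
    coverage_mode = "mature_plus_immature",
    model = list(include_year_dummies = TRUE, ref_year = 2018)
  )
}

#' Validate a run configuration
#'
#' @param config Config list or path to a YAML file.
#' @return Character vector of violations; empty iff the config is
#'   runnable.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(sprintf("config file '%s' does not exist", config))
    config <- yaml::read_yaml(config)
  }
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1, "seed: must be a single integer")
  chk(!is.null(config$out_dir), "out_dir: missing")
  chk(length(config$years) >= 2, "years: need at least 2 years")
  chk(is.numeric(config$n_plantations) && config$n_plantations >= 2,
      "n_plantations: need at least 2")
  tau <- config$compositing$tau
  chk(is.numeric(tau) && tau > 0, "compositing.tau: must be positive")
  chk(is.numeric(config$compositing$window) && config$compositing$window > 0,
      "compositing.window: must be positive")
  k <- config$kmeans$k
  chk(is.numeric(k) && k >= 2, "kmeans.k: must be at least 2")
  cf <- config$scene$cloud_fraction
  chk(is.numeric(cf) && cf >= 0 && cf <= 1, "scene.cloud_fraction: must be in [0, 1]")
  chk(config$coverage_mode %in% c("mature_plus_immature", "mature_only"),
      "coverage_mode: unknown mode")
  if (!is.null(config$kmeans$labeling)) {
    lab <- config$kmeans$labeling
    if (length(lab) != k) {
      v <- c(v, sprintf("kmeans.labeling: %d entries for k=%s (missing cluster %s)",
                        length(lab), k,
                        paste(setdiff(seq_len(k), seq_along(lab)), collapse = ",")))
    }
    bad <- setdiff(unique(unlist(lab)), COVER_CLASSES)
    if (length(bad)) v <- c(v, paste0("kmeans.labeling: unknown class ", bad))
  }
  for (pth in c(config$paths$polygons, config$paths$prices, config$paths$captures)) {
    if (!is.null(pth) && !file.exists(pth))
      v <- c(v, sprintf("paths: '%s' does not exist", pth))
  }
  v
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> composite -> classify -> indices -> coverage ->
#' panel -> models, writing every intermediate artifact (CSV/JSON) under
#' the configured output directory, and returns a run report. The k-means
#' model is fitted once on the first year's composite, labeled by
#' ground-truth majority, and its centroids frozen for all years.
#'
#' @param config Config list (see [demo_config()]) or path to a YAML file.
#' @return Run report list: per-stage counts, file paths, fit summaries.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config:\n  ", paste(viol, collapse = "\n  "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list())
  years <- as.integer(config$years)

  # --- simulate -----------------------------------------------------------
  spec <- scene_spec(width = config$scene$width, height = config$scene$height,
                     cloud_fraction = config$scene$cloud_fraction,
                     n_captures = config$scene$n_captures, seed = config$seed)
  series <- generate_scene_series(spec, years,
                                  annual_loss = config$scene$annual_loss)
  plantations <- generate_plantations(spec, n = config$n_plantations)
  write_plantations_geojson(plantations,
                            file.path(config$out_dir, "plantations.geojson"))
  report$stages$simulate <- list(years = length(series),
                                 plantations = length(plantations))

  # --- composite ----------------------------------------------------------
  composites <- lapply(seq_along(years), function(i)
    compose_annual(series[[i]]$captures, tau = config$compositing$tau,
                   window = config$compositing$window, year = years[i]))
  names(composites) <- as.character(years)
  report$stages$composite <- list(
    valid_fraction = vapply(composites, function(cm) mean(cm$valid_mask), 0))

  # --- land-cover model (fitted once, frozen) -----------------------------
  first <- composites[[1]]
  px <- sample_pixels(first, n = config$kmeans$sample_size, seed = config$seed)
  model <- fit_kmeans(px, k = config$kmeans$k, seed = config$seed)
  if (!is.null(config$kmeans$labeling)) {
    model <- label_clusters(model, unlist(config$kmeans$labeling))
  } else {
    idx <- which(first$valid_mask)
    xall <- vapply(S2_BANDS, function(b) first$bands[[b]][idx],
                   numeric(length(idx)))
    model <- label_clusters_by_truth(model, matrix(xall, ncol = 13),
                                     series[[1]]$truth_classes[idx])
  }
  write_cluster_model(model, file.path(config$out_dir, "cluster_model.json"))
  report$stages$kmeans <- list(k = model$k, inertia = model$fit_metadata$inertia,
                               labels = model$labels)

  # --- classify + coverage + indices --------------------------------------
  cov_rows <- list(); idx_rows <- list(); truth_rows <- list()
  for (i in seq_along(years)) {
    cg <- classify_composite(composites[[i]], model)
    cov_rows[[i]] <- coverage_table(cg, plantations, mode = config$coverage_mode)
    idx_rows[[i]] <- plantation_index_means(composites[[i]], plantations)
    truth_rows[[i]] <- data.frame(
      plantation_id = vapply(plantations, `[[`, "", "plantation_id"),
      year = years[i],
      truth_coverage = vapply(plantations, function(p)
        truth_coverage(series[[i]]$truth_classes, series[[i]]$gt, p,
                       mode = config$coverage_mode,
                       valid_mask = composites[[i]]$valid_mask), 0))
  }
  coverage <- do.call(rbind, cov_rows)
  indices <- do.call(rbind, idx_rows)
  truth <- do.call(rbind, truth_rows)
  write.csv(coverage, file.path(config$out_dir, "coverage.csv"), row.names = FALSE)
  write.csv(indices, file.path(config$out_dir, "indices.csv"), row.names = FALSE)
  write.csv(truth, file.path(config$out_dir, "coverage_truth.csv"), row.names = FALSE)
  report$stages$coverage <- list(rows = nrow(coverage))

  # --- panel + models -----------------------------------------------------
  prices <- default_price_table()
  plant_df <- do.call(rbind, lapply(plantations, function(p)
    data.frame(plantation_id = p$plantation_id, mill = p$mill, type = p$type,
               cert_year = p$cert_year)))
  panel <- build_panel(coverage, indices, plant_df, prices)
  write.csv(panel, file.path(config$out_dir, "panel.csv"), row.names = FALSE)
  report$stages$panel <- list(rows = nrow(panel),
                              dropped = attr(panel, "n_dropped"))

  fits <- list()
  for (ch in sort(unique(panel$cohort))) {
    sub <- panel[panel$cohort == ch, ]
    # a cohort must carry enough plantations and rows to identify the model
    if (length(unique(sub$plantation_id)) < 4 || length(unique(sub$year)) < 2 ||
        nrow(sub) < 30)
      next
    fits[[ch]] <- fit_random_effects(
      sub, include_year_dummies = isTRUE(config$model$include_year_dummies),
      ref_year = config$model$ref_year)
  }
  kw <- kruskal_wallis(panel$coverage, panel$type)
  dunn <- dunn_posthoc(panel$coverage, panel$type)
  report$stages$models <- list(
    cohorts = names(fits),
    fits = lapply(fits, function(f)
      list(coefficients = f$coefficients, marginal_r2 = f$marginal_r2,
           conditional_r2 = f$conditional_r2, log_likelihood = f$log_likelihood,
           aic = f$aic, bic = f$bic, n_obs = f$n_obs)),
    kruskal_wallis = kw,
    dunn = dunn)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
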