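#!/usr/bin/env Rscript

# Stage 5 -- panel assembly and the statistical battery.
#
# Joins coverage, index means, plantation attributes and the annual
# palm-oil price into the plantation-year panel, fits the random-intercept
# model (ML, year indicators against the 2018 reference) per certification
# cohort, and runs the Kruskal-Wallis / Dunn comparison of coverage across
# plantation types.

suppressMessages(library(palmwatch))

out <- "results"
coverage <- read.csv(file.path(out, "coverage.csv"))
indices <- read.csv(file.path(out, "indices.csv"))
plantations <- read_plantations_geojson(file.path(out, "plantations.geojson"))
prices <- read.csv(system.file("extdata", "prices.csv", package = "palmwatch"))

panel <- build_panel(coverage, indices, plantations, prices)
write.csv(panel, file.path(out, "panel.csv"), row.names = FALSE)
cat("Panel assembled:", nrow(panel), "plantation-year rows,",
    attr(panel, "n_dropped"), "dropped\n")

fits <- list()
for (ch in sort(unique(panel$cohort))) {
  sub <- panel[panel$cohort == ch, ]
  if (length(unique(sub$plantation_id)) < 4 || nrow(sub) < 30) {
    cat("\n--", ch, ": too few plantations for a cohort model, skipped\n")
    next
  }
  cat("\n--", ch, "(", length(unique(sub$plantation_id)), "plantations ) --\n")
  fit <- fit_random_effects(sub, include_year_dummies = TRUE, ref_year = 2018)
  print(fit)
  fits[[ch]] <- list(coefficients = fit$coefficients,
                     var_random = fit$var_random,
                     var_residual = fit$var_residual,
                     marginal_r2 = fit$marginal_r2,
                     conditional_r2 = fit$conditional_r2,
                     log_likelihood = fit$log_likelihood,
                     aic = fit$aic, bic = fit$bic, n_obs = fit$n_obs,
                     dropped_terms = fit$dropped_terms)
}

kw <- kruskal_wallis(panel$coverage, panel$type)
dunn <- dunn_posthoc(panel$coverage, panel$type)
cat(sprintf("\nKruskal-Wallis chi-squared = %.3f, df = %d, p = %.4g\n",
            kw$statistic, kw$df, kw$p_value))
cat("Dunn post-hoc (unadjusted two-tailed):\n")
print(dunn, digits = 3)

jsonlite::write_json(list(fits = fits, kruskal_wallis = kw, dunn = dunn),
                     file.path(out, "models.json"),
                     auto_unbox = TRUE, digits = NA, force = TRUE)
cat("\nModel summaries written to", file.path(out, "models.json"), "\n")
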