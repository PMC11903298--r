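test_that("a 48-plantation 7-year panel is balanced with 336 rows", {
  gp <- generate_panel(panel_spec(n_plantations = 48, years = 2017:2023, seed = 1))
  expect_equal(nrow(gp$panel), 336)
  expect_equal(length(unique(gp$panel$plantation_id)), 48)
  expect_true(all(table(gp$panel$plantation_id) == 7))
  # seeded determinism
  gp2 <- generate_panel(panel_spec(n_plantations = 48, years = 2017:2023, seed = 1))
  expect_identical(gp$panel, gp2$panel)
})

test_that("noise-free panels satisfy the linear model to machine precision", {
  ps <- panel_spec(n_plantations = 10, random_intercept_sd = 0,
                   residual_sd = 0, seed = 3)
  gp <- generate_panel(ps)
  b <- gp$truth$betas
  eta <- b[["intercept"]] + b[["self_produced"]] * gp$panel$self_produced +
    b[["outsourced"]] * gp$panel$outsourced + b[["ndvi"]] * gp$panel$ndvi +
    b[["ndmi"]] * gp$panel$ndmi + b[["bsi"]] * gp$panel$bsi +
    b[["price"]] * gp$panel$price
  for (yy in gp$truth$dummy_years)
    eta <- eta + b[[paste0("yr_", yy)]] * (gp$panel$year == yy)
  expect_equal(gp$panel$coverage, eta, tolerance = 1e-12)
})

test_that("panel specs validate their inputs", {
  expect_error(panel_spec(n_plantations = 1), "at least 2 plantations")
  expect_error(panel_spec(years = 2020), "at least 2 years")
  expect_error(panel_spec(type_shares = c(a = 0.5, b = 0.2, c = 0.2)), "sum to 1")
  expect_error(panel_spec(residual_sd = -1), "non-negative")
  expect_error(panel_spec(years = 2015:2020), "missing panel year")
})

test_that("the plantation register reproduces the cohort bookkeeping", {
  reg <- plantation_register(seed = 1)
  expect_equal(nrow(reg), 144)
  expect_equal(as.vector(table(reg$type)[c("own_estate", "outside_supplier_estate",
                                           "outside_supplier_smallgrower")]),
               c(28, 39, 77))
  expect_equal(sum(reg$cert_year == 2018), 48)
  expect_equal(sum(reg$area_ha), 135683)
  by_type <- tapply(reg$area_ha, reg$type, sum)
  expect_equal(as.numeric(by_type[c("own_estate", "outside_supplier_estate",
                                    "outside_supplier_smallgrower")]),
               c(33026, 90469, 12188))
  tab <- table(reg$type, reg$cert_year)
  expect_equal(unname(tab["own_estate", "2018"]), 5)
  expect_equal(unname(tab["outside_supplier_estate", "2018"]), 11)
  expect_equal(unname(tab["outside_supplier_smallgrower", "2018"]), 32)
})

test_that("build_panel joins, derives cohorts, and guards its contracts", {
  cov <- expand.grid(plantation_id = c("A", "B"), year = 2018:2019,
                     stringsAsFactors = FALSE)
  cov$coverage <- c(0.8, 0.7, 0.75, NA)
  idx <- cov[c("plantation_id", "year")]
  idx$ndvi <- 0.7; idx$ndmi <- 0.5; idx$bsi <- -0.4
  pl <- data.frame(plantation_id = c("A", "B"), mill = "M01",
                   type = c("own_estate", "outside_supplier_smallgrower"),
                   cert_year = c(2018, 2023))
  pr <- data.frame(year = 2018:2019, price = c(1940, 3050))
  expect_message(panel <- build_panel(cov, idx, pl, pr), "dropping 1")
  expect_equal(nrow(panel), 3)
  expect_equal(attr(panel, "n_dropped"), 1L)
  expect_equal(panel$cohort[panel$plantation_id == "A"][1], "certified-2018")
  expect_equal(panel$self_produced[panel$plantation_id == "A"][1], 1L)
  expect_equal(panel$price[panel$year == 2018][1], 1940)
  # empty coverage -> empty panel, no error
  expect_equal(nrow(build_panel(cov[0, ], idx, pl, pr)), 0)
  # duplicates and missing prices are contract violations
  expect_error(build_panel(rbind(cov, cov[1, ]), idx, pl, pr), "duplicate")
  expect_error(build_panel(cov, idx, pl, pr[1, , drop = FALSE]),
               "missing year")
})

test_that("zero random-intercept data collapses to pooled OLS", {
  # residual noise centred within each plantation leaves no between-group
  # variance, so the ML estimate of the random-intercept variance hits the
  # zero boundary and the fixed effects equal pooled OLS
  ps <- panel_spec(n_plantations = 30, random_intercept_sd = 0,
                   residual_sd = 0, seed = 6)
  gp <- generate_panel(ps)
  withr::with_seed(1, {
    eps <- rnorm(nrow(gp$panel), 0, 0.05)
  })
  eps <- eps - ave(eps, gp$panel$plantation_id)
  gp$panel$coverage <- gp$panel$coverage + eps
  fit <- fit_random_effects(gp$panel)
  expect_lt(fit$var_random, 1e-8)
  X <- palmwatch:::panel_design(gp$panel, TRUE, 2018)$X
  ols <- stats::lm.fit(X, gp$panel$coverage)
  expect_equal(unname(fit$coefficients$estimate),
               unname(ols$coefficients), tolerance = 1e-6)
})

test_that("fit statistics are internally consistent", {
  gp <- generate_panel(panel_spec(n_plantations = 40, seed = 8))
  fit <- fit_random_effects(gp$panel)
  expect_gte(fit$conditional_r2, fit$marginal_r2)
  expect_equal(fit$n_obs, nrow(gp$panel))
  # AIC/BIC identities from the ML log-likelihood
  k <- nrow(fit$coefficients) + 2 # fixed effects + RE variance + residual
  expect_equal(fit$aic, 2 * k - 2 * fit$log_likelihood, tolerance = 1e-8)
  expect_equal(fit$bic, k * log(fit$n_obs) - 2 * fit$log_likelihood,
               tolerance = 1e-8)
  # the final-year indicator is aliased with the annual price
  expect_identical(fit$dropped_terms, "yr_2023")
  # model without year indicators nests inside and cannot fit better
  fit0 <- fit_random_effects(gp$panel, include_year_dummies = FALSE)
  expect_lte(fit0$log_likelihood, fit$log_likelihood)
  expect_error(fit_random_effects(gp$panel[gp$panel$plantation_id == "P001", ]),
               "fewer than 2")
})

test_that("true coefficients are covered by 95% Wald intervals in >=90% of replicates", {
  terms_checked <- c("self_produced", "ndvi", "bsi", "yr_2019", "yr_2021")
  hits <- matrix(0, 0, length(terms_checked))
  for (s in 1:100) {
    gp <- generate_panel(panel_spec(n_plantations = 200, residual_sd = 0.05,
                                    random_intercept_sd = 0.1, seed = 1000 + s))
    fit <- fit_random_effects(gp$panel)
    co <- fit$coefficients
    row <- vapply(terms_checked, function(tm) {
      i <- match(tm, co$term)
      truth <- gp$truth$betas[[tm]]
      abs(co$estimate[i] - truth) <= qnorm(0.975) * co$se[i]
    }, TRUE)
    hits <- rbind(hits, row)
  }
  expect_true(all(colMeans(hits) >= 0.90))
})

test_that("Kruskal-Wallis matches the rank-sum oracle and the permutation null", {
  vals <- c(1, 4, 2, 5, 3, 6)
  grp <- rep(c("a", "b", "c"), each = 2)
  got <- kruskal_wallis(vals, grp)
  expect_equal(got$df, 2)
  expect_equal(got$statistic, oracle_kw_h(vals, grp), tolerance = 1e-12)
  # full enumeration of the permutation null on 6 observations
  perms <- combn(6, 2)
  h_obs <- got$statistic
  all_h <- c()
  for (i in seq_len(ncol(perms))) {
    rest <- setdiff(1:6, perms[, i])
    inner <- combn(rest, 2)
    for (j in seq_len(ncol(inner))) {
      g <- integer(6)
      g[perms[, i]] <- 1L; g[inner[, j]] <- 2L; g[g == 0L] <- 3L
      all_h <- c(all_h, oracle_kw_h(vals, g))
    }
  }
  perm_p <- mean(all_h >= h_obs - 1e-12)
  # the chi-squared p is an approximation; the exact null must agree coarsely
  expect_lt(abs(got$p_value - perm_p), 0.15)
})

test_that("KW on two groups equals the Wilcoxon chi-squared form", {
  withr::with_seed(2, {
    x <- rnorm(8); y <- rnorm(6, 0.5)
  })
  got <- kruskal_wallis(c(x, y), rep(c("x", "y"), c(8, 6)))
  expect_equal(got$df, 1)
  expect_equal(got$statistic, oracle_wilcoxon_chisq(x, y), tolerance = 1e-10)
})

test_that("interleaved identical groups give H near zero, p near one", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8)
  grp <- rep(c("a", "b"), 4)
  got <- kruskal_wallis(vals, grp)
  expect_lt(got$statistic, 0.5)
  expect_gt(got$p_value, 0.4)
})

test_that("degenerate Kruskal-Wallis inputs are rejected", {
  expect_error(kruskal_wallis(1:6, rep("a", 6)), "at least 2 groups")
  expect_error(kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3)), "identical")
  expect_error(kruskal_wallis(1:4, factor(rep(c("a", "b"), 2),
                                          levels = c("a", "b", "c"))),
               "empty group")
})

test_that("Dunn z matches the hand formula, signs follow rank order", {
  vals <- c(12, 14, 15, 3, 5, 7, 9, 1, 2, 4)
  grp <- rep(c("hi", "mid", "lo"), c(3, 4, 3))
  got <- dunn_posthoc(vals, grp)
  for (i in seq_len(nrow(got))) {
    expect_equal(got$z[i],
                 unname(oracle_dunn_z(vals, grp, got$group1[i], got$group2[i])),
                 tolerance = 1e-12)
  }
  # stochastically larger group gets positive z when listed first
  z_hi_lo <- got$z[got$group1 == "hi" & got$group2 == "lo"]
  expect_gt(z_hi_lo, 0)
  # swapped order negates z, keeps p
  g2 <- factor(grp, levels = c("mid", "lo", "hi"))
  got2 <- dunn_posthoc(vals, g2)
  z_lo_hi <- got2$z[got2$group1 == "lo" & got2$group2 == "hi"]
  expect_equal(z_lo_hi, -z_hi_lo)
  expect_equal(got2$p_value[got2$group1 == "lo" & got2$group2 == "hi"],
               got$p_value[got$group1 == "hi" & got$group2 == "lo"])
  # Holm adjustment never lowers a p-value
  gh <- dunn_posthoc(vals, grp, adjust = "holm")
  expect_true(all(gh$p_value >= got$p_value - 1e-15))
  expect_error(dunn_posthoc(1:5, rep("a", 5)), "at least 2 groups")
})

test_that("ties are handled identically by both rank tests", {
  vals <- c(1, 1, 2, 3, 3, 3, 4, 5, 5, 6)
  grp <- rep(c("a", "b"), 5)
  expect_equal(kruskal_wallis(vals, grp)$statistic, oracle_kw_h(vals, grp),
               tolerance = 1e-12)
  dz <- dunn_posthoc(vals, grp)
  expect_equal(dz$z[1], unname(oracle_dunn_z(vals, grp, "a", "b")),
               tolerance = 1e-12)
})
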