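#' Default annual Malaysian palm-oil price table (MYR per metric ton)
#'
#' Dec-31 exchange-date trade prices used as the price regressor. The 2018
#' trough (1940) and 2021 peak (5046) anchor the series; intervening years
#' are plausible interpolations treated as fixed generator configuration.
#'
#' @return data.frame with columns `year`, `price`.
#' @export
default_price_table <- function() {
  data.frame(
    year = 2017:2023,
    price = c(2470, 1940, 3050, 3800, 5046, 4160, 3700)
  )
}

#' Plantation register reproducing the published cohort bookkeeping
#'
#' 144 plantations split across the three management types (28 own
#' estates, 39 outside supplier estates, 77 outside supplier small
#' growers) and two certification cohorts (48 certified in 2018 of which
#' 5/11/32 by type; 96 certified in 2023), with per-type total areas of
#' 33,026 / 90,469 / 12,188 ha allocated across plantations by a seeded
#' draw under a largest-remainder rounding that keeps the printed totals
#' exact.
#'
#' @param seed Integer seed for the within-type area allocation.
#' @return data.frame: plantation_id, mill, type, cert_year, area_ha.
#' @export
plantation_register <- function(seed = 1) {
  types <- c("own_estate", "outside_supplier_estate", "outside_supplier_smallgrower")
  n_type <- c(28, 39, 77)
  n_2018 <- c(5, 11, 32)
  area_type <- c(33026, 90469, 12188)
  mills <- sprintf("M%02d", 1:6) # three mills certified 2018, three 2023
  rows <- list()
  with_seed(seed, {
    for (t in seq_along(types)) {
      n <- n_type[t]
      # lognormal share draw, scaled to the printed type total, integer ha
      w <- exp(rnorm(n, 0, 0.6))
      raw <- area_type[t] * w / sum(w)
      a <- floor(raw)
      rem <- area_type[t] - sum(a)
      a[order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]] <- a[order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]] + 1
      cert <- c(rep(2018, n_2018[t]), rep(2023, n - n_2018[t]))
      mill <- ifelse(cert == 2018, mills[sample.int(3, n, replace = TRUE)],
                     mills[3 + sample.int(3, n, replace = TRUE)])
      rows[[t]] <- data.frame(
        plantation_id = sprintf("%s_%03d", c("OE", "OS", "SG")[t], seq_len(n)),
        mill = mill, type = types[t], cert_year = cert, area_ha = a
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Panel specification for the synthetic panel generator
#'
#' Defines a balanced plantation-year panel whose coverage outcome follows
#' a known linear mixed model: type dummies (small-grower baseline), the
#' three spectral-index means, the annual price, and year indicators with
#' 2018 as reference. The final panel year carries no own indicator
#' because the annual price, constant within years, already absorbs one
#' year degree of freedom; the published model table follows the same
#' identification.
#'
#' @param n_plantations Number of plantations (>= 2).
#' @param years Ordered calendar years (>= 2; default 2017:2023).
#' @param true_betas Named coefficient vector (coverage-fraction units):
#'   `intercept`, `self_produced`, `outsourced`, `ndvi`, `ndmi`, `bsi`,
#'   `price`, and `yr_<year>` for every non-reference, non-final year.
#' @param random_intercept_sd Plantation random-intercept sd (>= 0).
#' @param residual_sd Residual sd (> 0 for stochastic panels; 0 allowed
#'   for the noise-free limit).
#' @param type_shares Proportions of own estate / outside supplier estate /
#'   small grower; must sum to 1. Defaults follow the 28/39/77 register.
#' @param prices data.frame year, price covering all panel years.
#' @param index_levels List of mean/sd for the ndvi, ndmi, bsi regressors.
#' @param seed Integer seed.
#' @return Object of class `panel_spec`.
#' @export
panel_spec <- function(n_plantations = 48, years = 2017:2023,
                       true_betas = NULL,
                       random_intercept_sd = 0.10, residual_sd = 0.05,
                       type_shares = c(own_estate = 28 / 144,
                                       outside_supplier_estate = 39 / 144,
                                       outside_supplier_smallgrower = 77 / 144),
                       prices = default_price_table(),
                       index_levels = list(ndvi = c(0.70, 0.03),
                                           ndmi = c(0.50, 0.03),
                                           bsi  = c(-0.45, 0.05)),
                       seed = 1) {
  if (n_plantations < 2) stop("need at least 2 plantations")
  if (length(years) < 2) stop("need at least 2 years")
  if (abs(sum(type_shares) - 1) > 1e-8) stop("type_shares must sum to 1")
  if (residual_sd < 0 || random_intercept_sd < 0)
    stop("variance components must be non-negative")
  if (!all(years %in% prices$year)) stop("price table missing panel year(s)")
  years <- sort(years)
  ref_year <- if (2018 %in% years) 2018 else years[1]
  dummy_years <- setdiff(years, c(ref_year, years[length(years)]))
  if (is.null(true_betas)) {
    true_betas <- c(
      intercept = -0.70, self_produced = 0.041, outsourced = -0.017,
      ndvi = 0.75, ndmi = 0.50, bsi = -1.20, price = 2e-5,
      setNames(c(0.004, -0.080, -0.052, -0.195, -0.252)[seq_along(dummy_years)],
               paste0("yr_", dummy_years))
    )
  }
  need <- c("intercept", "self_produced", "outsourced", "ndvi", "ndmi", "bsi",
            "price", paste0("yr_", dummy_years))
  miss <- setdiff(need, names(true_betas))
  if (length(miss)) stop("true_betas missing: ", paste(miss, collapse = ", "))
  structure(list(n_plantations = n_plantations, years = years,
                 ref_year = ref_year, dummy_years = dummy_years,
                 true_betas = true_betas[need],
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd, type_shares = type_shares,
                 prices = prices, index_levels = index_levels, seed = seed),
            class = "panel_spec")
}

#' Generate a balanced plantation-year panel with known coefficients
#'
#' One row per plantation and year; coverage = X beta + plantation random
#' intercept + residual noise, with the design described in
#' [panel_spec()]. The returned truth record carries the coefficient
#' vector and the drawn random intercepts so recovery can be checked
#' exactly.
#'
#' @param spec A [panel_spec()].
#' @return List: `panel` (data.frame of panel rows) and `truth`
#'   (true_betas, random_intercepts, variance components).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    n <- spec$n_plantations
    years <- spec$years
    # deterministic type assignment honouring the shares as closely as possible
    n_by_type <- floor(spec$type_shares * n)
    rem <- n - sum(n_by_type)
    frac <- spec$type_shares * n - n_by_type
    if (rem > 0) {
      bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
      n_by_type[bump] <- n_by_type[bump] + 1
    }
    type <- rep(names(spec$type_shares), times = n_by_type)
    b_i <- rnorm(n, 0, spec$random_intercept_sd)
    rows <- expand.grid(plantation_id = sprintf("P%03d", seq_len(n)),
                        year = years, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    rows <- rows[order(rows$plantation_id, rows$year), ]
    rownames(rows) <- NULL
    pid_num <- match(rows$plantation_id, sprintf("P%03d", seq_len(n)))
    rows$mill <- sprintf("M%02d", (pid_num - 1) %% 6 + 1)
    rows$type <- type[pid_num]
    rows$self_produced <- as.integer(rows$type == "own_estate")
    rows$outsourced <- as.integer(rows$type == "outside_supplier_estate")
    for (ix in c("ndvi", "ndmi", "bsi")) {
      lv <- spec$index_levels[[ix]]
      rows[[ix]] <- rnorm(nrow(rows), lv[1], lv[2])
    }
    rows$price <- spec$prices$price[match(rows$year, spec$prices$year)]
    bet <- spec$true_betas
    eta <- bet[["intercept"]] +
      bet[["self_produced"]] * rows$self_produced +
      bet[["outsourced"]] * rows$outsourced +
      bet[["ndvi"]] * rows$ndvi + bet[["ndmi"]] * rows$ndmi +
      bet[["bsi"]] * rows$bsi + bet[["price"]] * rows$price
    for (yy in spec$dummy_years)
      eta <- eta + bet[[paste0("yr_", yy)]] * (rows$year == yy)
    eps <- if (spec$residual_sd > 0) rnorm(nrow(rows), 0, spec$residual_sd) else 0
    rows$coverage <- eta + b_i[pid_num] + eps
    rows$cohort <- "certified-2018"
    list(panel = rows,
         truth = list(betas = bet, random_intercepts = b_i,
                      random_intercept_sd = spec$random_intercept_sd,
                      residual_sd = spec$residual_sd,
                      ref_year = spec$ref_year, dummy_years = spec$dummy_years))
  })
}
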