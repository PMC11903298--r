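#' Assemble the plantation-year panel
#'
#' Joins coverage records, per-plantation-year index means, plantation
#' attributes and the annual price table into one row per plantation-year.
#' The certification cohort is derived from the plantation's certification
#' year; rows with missing coverage are dropped with a logged count.
#'
#' @param coverage data.frame with plantation_id, year, coverage.
#' @param indices data.frame with plantation_id, year, ndvi, ndmi, bsi.
#' @param plantations data.frame with plantation_id, mill, type, cert_year
#'   (e.g. [plantation_register()]), or a list of plantation records.
#' @param prices data.frame year, price covering every panel year.
#' @return data.frame of panel rows with attribute `n_dropped`.
#' @export
build_panel <- function(coverage, indices, plantations, prices) {
  if (is.list(plantations) && !is.data.frame(plantations))
    plantations <- do.call(rbind, lapply(plantations, function(p)
      data.frame(plantation_id = p$plantation_id, mill = p$mill,
                 type = p$type, cert_year = p$cert_year)))
  if (nrow(coverage) == 0) {
    out <- coverage[0, , drop = FALSE]
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  if (anyDuplicated(coverage[c("plantation_id", "year")]))
    stop("duplicate plantation-year in coverage input")
  miss_price <- setdiff(unique(coverage$year), prices$year)
  if (length(miss_price))
    stop("price table missing year(s): ", paste(miss_price, collapse = ", "))
  panel <- merge(coverage, indices, by = c("plantation_id", "year"))
  panel <- merge(panel, plantations[c("plantation_id", "mill", "type", "cert_year")],
                 by = "plantation_id")
  panel$price <- prices$price[match(panel$year, prices$year)]
  panel$self_produced <- as.integer(panel$type == "own_estate")
  panel$outsourced <- as.integer(panel$type == "outside_supplier_estate")
  panel$cohort <- paste0("certified-", panel$cert_year)
  dropped <- sum(is.na(panel$coverage))
  if (dropped > 0) {
    message("build_panel: dropping ", dropped, " row(s) with missing coverage")
    panel <- panel[!is.na(panel$coverage), ]
  }
  panel <- panel[order(panel$plantation_id, panel$year), ]
  rownames(panel) <- NULL
  attr(panel, "n_dropped") <- dropped
  panel
}

# Fixed-effect design for the coverage model. Year indicators are coded
# against the 2018 reference; aliased columns (detected by QR pivoting,
# e.g. the final-year indicator when the within-year-constant price is
# present) are dropped with their names recorded.
panel_design <- function(panel, include_year_dummies = TRUE, ref_year = 2018) {
  X <- cbind(`(Intercept)` = 1,
             self_produced = panel$self_produced,
             outsourced = panel$outsourced,
             ndvi = panel$ndvi, ndmi = panel$ndmi, bsi = panel$bsi,
             price = panel$price)
  if (include_year_dummies) {
    yrs <- sort(unique(panel$year))
    if (!ref_year %in% yrs) ref_year <- yrs[1]
    for (yy in setdiff(yrs, ref_year)) {
      d <- as.numeric(panel$year == yy)
      X <- cbind(X, setNames(data.frame(d), paste0("yr_", yy)))
    }
    X <- as.matrix(X)
  }
  q <- qr(X)
  dropped <- character(0)
  if (q$rank < ncol(X)) {
    keep <- q$pivot[seq_len(q$rank)]
    dropped <- colnames(X)[-keep]
    X <- X[, sort(keep), drop = FALSE]
  }
  list(X = X, dropped = dropped)
}

#' Fit the random-intercept coverage model
#'
#' Linear mixed model of plantation coverage on the fixed regressors
#' (type dummies with the small-grower baseline, the three index means,
#' the annual price, and optionally year indicators against the 2018
#' reference) with a random intercept per plantation, estimated by maximum
#' likelihood so that log-likelihoods, AIC and BIC are comparable across
#' nested specifications. p-values are two-tailed Wald z. Marginal and
#' conditional R-squared follow the variance-partition formulation
#' (fixed-effect variance over total; fixed plus random over total).
#'
#' @param panel data.frame of one cohort's panel rows (see
#'   [build_panel()] or [generate_panel()]).
#' @param include_year_dummies Include year indicators (default TRUE).
#' @param ref_year Reference year for the indicators (default 2018).
#' @param group Grouping column for the random intercept (default
#'   "plantation_id"; set "mill" for mill-level nesting).
#' @return Object of class `panel_fit`: `coefficients` (data.frame with
#'   estimate, se, z, p), `var_random`, `var_residual`, `marginal_r2`,
#'   `conditional_r2`, `log_likelihood`, `aic`, `bic`, `n_obs`,
#'   `n_groups`, `dropped_terms`.
#' @export
fit_random_effects <- function(panel, include_year_dummies = TRUE,
                               ref_year = 2018, group = "plantation_id") {
  if (length(unique(panel[[group]])) < 2) stop("fewer than 2 groups")
  if (length(unique(panel$year)) < 2) stop("fewer than 2 years")
  des <- panel_design(panel, include_year_dummies, ref_year)
  X <- des$X
  dat <- as.data.frame(X[, -1, drop = FALSE])
  dat$coverage <- panel$coverage
  dat$.group <- panel[[group]]
  rhs <- paste(sprintf("`%s`", setdiff(colnames(X), "(Intercept)")),
               collapse = " + ")
  fml <- as.formula(paste("coverage ~", rhs, "+ (1 | .group)"))
  fit <- lme4::lmer(fml, data = dat, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                check.scaleX = "ignore"))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  vc <- lme4::VarCorr(fit)
  var_re <- as.numeric(vc$.group[1, 1])
  var_res <- stats::sigma(fit)^2
  var_fix <- var(as.numeric(X %*% beta))
  tot <- var_fix + var_re + var_res
  ll <- as.numeric(logLik(fit))
  structure(
    list(coefficients = data.frame(term = names(beta), estimate = unname(beta),
                                   se = unname(se), z = unname(z), p = unname(p)),
         var_random = var_re, var_residual = var_res,
         marginal_r2 = var_fix / tot, conditional_r2 = (var_fix + var_re) / tot,
         log_likelihood = ll, aic = AIC(fit), bic = BIC(fit),
         n_obs = nrow(dat), n_groups = length(unique(dat$.group)),
         dropped_terms = des$dropped, group = group,
         include_year_dummies = include_year_dummies),
    class = "panel_fit"
  )
}

#' @export
print.panel_fit <- function(x, ...) {
  stars <- function(p) ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "")))
  cat("Random-intercept coverage model (ML)\n")
  co <- x$coefficients
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %-14s %9.4f%-3s (%.4f)\n", co$term[i], co$estimate[i],
                stars(co$p[i]), co$se[i]))
  if (length(x$dropped_terms))
    cat("  [aliased, dropped:", paste(x$dropped_terms, collapse = ", "), "]\n")
  cat(sprintf("  Observations   %d (groups: %d)\n", x$n_obs, x$n_groups))
  cat(sprintf("  Marginal R2    %.3f\n  Conditional R2 %.3f\n", x$marginal_r2,
              x$conditional_r2))
  cat(sprintf("  Log likelihood %.3f\n  AIC %.3f   BIC %.3f\n",
              x$log_likelihood, x$aic, x$bic))
  cat("  *p<0.05 **p<0.01 ***p<0.001 (two-tailed)\n")
  invisible(x)
}

#' Kruskal-Wallis rank-sum test across plantation types
#'
#' Tie-corrected H statistic with a chi-squared reference distribution on
#' (number of groups - 1) degrees of freedom.
#'
#' @param values Numeric vector (e.g. coverage).
#' @param groups Factor or character vector of group membership.
#' @return List: `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  if (is.factor(groups) && any(table(groups) == 0)) stop("empty group")
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(unique(values)) == 1)
    stop("all values identical: tie correction degenerate")
  kt <- kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Dunn's post-hoc test for pairwise group differences
#'
#' Pairwise z statistics from pooled mid-ranks with the usual tie
#' correction; the sign convention is positive z when the first group of
#' the pair has the larger mean rank. Unadjusted two-tailed p-values by
#' default, with an optional Holm adjustment.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector.
#' @param adjust "none" (default) or "holm".
#' @return data.frame: group1, group2, z, p_value.
#' @export
dunn_posthoc <- function(values, groups, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(pr) {
    sig <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[pr[1]] + 1 / n_g[pr[2]]))
    (mean_rank[pr[1]] - mean_rank[pr[2]]) / sig
  })
  p <- 2 * pnorm(-abs(z))
  if (adjust == "holm") p <- p.adjust(p, "holm")
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = unname(z), p_value = unname(p))
}
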