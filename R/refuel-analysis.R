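# Two-tier AICc analysis of refueling index values: a methodological tier
# (bleed time, time of day, date, year) whose winning terms are carried
# into a biological tier (breeding destination, timing, condition, age,
# sex, with second-order interactions).

#' Default tier specifications for the refueling analysis
#'
#' Tier 1 screens four methodological covariates (ln bleed time, minutes
#' since sunrise, day of year, year) in all subset combinations (15 models
#' plus a null). Tier 2 crosses breeding destination, timing class,
#' migratory condition, age and sex with the biologically meaningful
#' second-order interactions (breeding with timing/age/sex, timing with
#' age/sex), the tier-1 winners forced into every non-null model; with the
#' defaults this enumerates 144 candidate models including the null.
#'
#' @return List with `tier1_terms`, `tier2_terms`, `tier2_interactions`.
#' @export
default_refuel_tiers <- function() {
  list(tier1_terms = c("ln_bleedtime", "daytime", "season", "year"),
       tier2_terms = c("destination", "timing", "condition", "age", "sex"),
       tier2_interactions = c("destination:timing", "destination:age",
                              "destination:sex", "timing:age", "timing:sex"))
}

set_reference_levels <- function(df) {
  relev <- function(x, ref) {
    x <- factor(x)
    if (ref %in% levels(x)) stats::relevel(x, ref) else x
  }
  if ("sex" %in% names(df)) df$sex <- relev(df$sex, "F")
  if ("age" %in% names(df)) df$age <- relev(df$age, "SY")
  if ("destination" %in% names(df)) df$destination <- relev(df$destination, "southeast")
  if ("timing" %in% names(df)) df$timing <- relev(as.character(df$timing), "early")
  if ("year" %in% names(df)) df$year <- factor(df$year)
  df
}

run_tier <- function(response, specs, data, delta_max = 4) {
  fits <- lapply(specs, function(tt) fit_refuel_model(response, tt, data))
  aic_table(fits, delta_max = delta_max)
}

#' Two-tier refueling-index model selection
#'
#' Computes the refueling index from all plasma samples (including birds
#' without an assigned destination), screens methodological covariates
#' (tier 1), carries the terms of the single lowest-AICc tier-1 model into
#' every non-null tier-2 model, and runs the biological tier on the birds
#' with destination and timing assignments. Reference levels: sex F, age
#' SY, destination southeast, timing early.
#'
#' @param plasma Plasma table: `bird_id`, `triglyceride`, `bohb`,
#'   `bleedtime`, `daytime`, `season` (day-of-year), `year`.
#' @param birds Bird table: `bird_id`, `destination`, `timing`,
#'   `condition`, `age`, `sex`.
#' @param tiers Tier specification, see [default_refuel_tiers()].
#' @param delta_max Competing-set threshold (default 4).
#' @return Object of class `refuel_analysis`: list with `index`
#'   (`refuel_index`), `tier1`, `tier2` (`aictab`s), `tier1_winners`,
#'   `averaged` (coefficient table: estimate, unconditional SE, relative
#'   importance), `group_means` (predicted index by destination x timing
#'   with unconditional SEs), `n_candidates`.
#' @export
two_tier_refueling_analysis <- function(plasma, birds,
                                        tiers = default_refuel_tiers(),
                                        delta_max = 4) {
  stopifnot(nrow(plasma) > 0)
  plasma <- transform_metabolites(plasma)
  idx <- refueling_index(plasma)
  plasma$refuel <- idx$scores

  t1 <- plasma
  t1$year <- factor(t1$year)
  t1_specs <- enumerate_candidate_models(tiers$tier1_terms)
  tier1 <- run_tier("refuel", t1_specs, t1, delta_max)
  winners <- tier1$fits[[1]]$terms

  joined <- merge(plasma, birds, by = "bird_id")
  joined <- joined[!is.na(joined$destination) &
                     joined$destination != "unassigned" &
                     !is.na(joined$timing), , drop = FALSE]
  if (nrow(joined) == 0L) stop("empty join of plasma and bird tables", call. = FALSE)
  joined <- set_reference_levels(joined)

  t2_specs <- enumerate_candidate_models(tiers$tier2_terms,
                                         tiers$tier2_interactions,
                                         always_include = winners)
  tier2 <- run_tier("refuel", t2_specs, joined, delta_max)

  # averaged coefficients over the competing set, with w+ over all candidates
  top_fits <- tier2$fits[top_set(tier2)]
  coef_names <- setdiff(unique(unlist(lapply(top_fits, function(f) names(f$coef)))),
                        "(Intercept)")
  averaged <- do.call(rbind, lapply(coef_names, function(cn) {
    ma <- model_average(tier2, cn)
    data.frame(coefficient = cn, estimate = ma$estimate, se = ma$se,
               n_models = ma$n_models, w_plus = ma$w_plus,
               stringsAsFactors = FALSE)
  }))

  gm <- refuel_group_means(tier2, joined)

  structure(list(index = idx, tier1 = tier1, tier2 = tier2,
                 tier1_winners = winners, averaged = averaged,
                 group_means = gm, n_candidates = length(t2_specs),
                 data = joined),
            class = "refuel_analysis")
}

# model-averaged predicted refueling index per destination x timing cell,
# continuous covariates held at their sample means, other factors at their
# reference level; unconditional SEs over the competing set
refuel_group_means <- function(tab, data) {
  in_top <- top_set(tab)
  w <- tab$table$weight[in_top]
  w <- w / sum(w)
  fits <- tab$fits[in_top]
  grid <- expand.grid(destination = levels(data$destination),
                      timing = levels(data$timing),
                      stringsAsFactors = FALSE)
  grid$destination <- factor(grid$destination, levels(data$destination))
  grid$timing <- factor(grid$timing, levels(data$timing))
  for (v in setdiff(names(data), c("destination", "timing"))) {
    grid[[v]] <- if (is.numeric(data[[v]])) mean(data[[v]])
                 else factor(levels(factor(data[[v]]))[1],
                             levels = levels(factor(data[[v]])))
  }
  preds <- lapply(fits, function(f) {
    stats::predict(f$fit, newdata = grid, se.fit = TRUE)
  })
  est <- sapply(preds, function(p) p$fit)
  sef <- sapply(preds, function(p) p$se.fit)
  mbar <- as.numeric(est %*% w)
  se_u <- vapply(seq_len(nrow(grid)), function(i) {
    sum(w * sqrt(sef[i, ]^2 + (est[i, ] - mbar[i])^2))
  }, numeric(1))
  data.frame(destination = grid$destination, timing = grid$timing,
             refuel = mbar, se = se_u, stringsAsFactors = FALSE)
}

#' @export
print.refuel_analysis <- function(x, ...) {
  cat("Two-tier refueling-index analysis\n")
  cat(sprintf("  PC1 variance explained: %.1f%% (loadings %+.2f / %+.2f)\n",
              100 * x$index$var_explained, x$index$loadings[1], x$index$loadings[2]))
  cat(sprintf("  tier-1 winner: %s\n", spec_label(x$tier1_winners)))
  cat(sprintf("  tier-2 candidates: %d; competing models (delta <= %g): %d\n",
              x$n_candidates, x$tier2$delta_max, sum(top_set(x$tier2))))
  cat("  model-averaged effects:\n")
  av <- x$averaged
  av$estimate <- round(av$estimate, 3); av$se <- round(av$se, 3)
  av$w_plus <- round(av$w_plus, 2)
  print(av, row.names = FALSE)
  invisible(x)
}
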