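# Migratory condition, range-based timing classes, and food-availability
# trend summaries.

#' Size-specific fat-free mass from wing chord
#'
#' Lean-mass regression estimated from long-term banding data at the study
#' site: `fat-free mass = 0.014 * wing chord + 2.0086`.
#'
#' Note: with the published coefficients the predicted lean mass for
#' realistic warbler wing chords (55-70 mm) is ~2.8-3.0 g, well below a
#' typical ~10 g body mass; the published equation likely carries a units
#' typo. It is applied verbatim here, with both coefficients configurable.
#'
#' @param wing_chord Wing chord in mm (must be positive). Vectorised.
#' @param slope,intercept Regression coefficients (defaults as published).
#' @return Fat-free mass in g.
#' @export
fat_free_mass <- function(wing_chord, slope = 0.014, intercept = 2.0086) {
  if (any(wing_chord <= 0)) stop("wing_chord must be positive", call. = FALSE)
  slope * wing_chord + intercept
}

#' Migratory condition index
#'
#' Body mass at capture minus size-specific fat-free mass; larger values
#' indicate more fat stores (better migratory condition). May be negative.
#'
#' @param body_mass Body mass in g (positive). Vectorised.
#' @param wing_chord Wing chord in mm (positive).
#' @param ... Passed to [fat_free_mass()].
#' @return Condition index in g.
#' @export
condition_index <- function(body_mass, wing_chord, ...) {
  if (any(body_mass <= 0)) stop("body_mass must be positive", call. = FALSE)
  body_mass - fat_free_mass(wing_chord, ...)
}

#' Split capture dates into early/middle/late timing classes
#'
#' Within each year x sex x destination group, the capture-date range is
#' divided into three equal periods; cut points fall at one third and two
#' thirds of the range. Intervals are left-closed (a date exactly on a cut
#' point belongs to the later class) and the final interval is closed. A
#' group whose dates span zero days is labelled `"middle"` with a warning.
#'
#' @param records Data frame with `day_of_year` plus the grouping columns.
#' @param group_keys Character vector of grouping columns
#'   (default `c("year", "sex", "destination")`).
#' @return `records` with a `timing` factor (`early`, `middle`, `late`).
#' @export
assign_timing_classes <- function(records,
                                  group_keys = c("year", "sex", "destination")) {
  stopifnot(is.data.frame(records), "day_of_year" %in% names(records),
            all(group_keys %in% names(records)))
  if (any(is.na(records$day_of_year))) stop("missing capture dates", call. = FALSE)
  timing <- rep(NA_character_, nrow(records))
  grp <- interaction(records[group_keys], drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    d <- records$day_of_year[idx]
    dmin <- min(d); dmax <- max(d)
    if (dmax == dmin) {
      warning(sprintf("group %s has zero capture-date range; all 'middle'", g),
              call. = FALSE)
      timing[idx] <- "middle"
      next
    }
    c1 <- dmin + (dmax - dmin) / 3
    c2 <- dmin + 2 * (dmax - dmin) / 3
    timing[idx] <- ifelse(d < c1, "early", ifelse(d < c2, "middle", "late"))
  }
  records$timing <- factor(timing, levels = c("early", "middle", "late"))
  records
}

#' Within-season and among-year trends in arthropod abundance
#'
#' Abundance (arthropods per g dry vegetation) is regressed on day-of-year
#' (ordinary least squares, within seasons pooled) and compared among years
#' with a one-way ANOVA.
#'
#' @param samples Data frame with columns `day_of_year`, `year`, `count`
#'   and `veg_mass_g` (or a precomputed `abundance`).
#' @return List with `slope`, `slope_p`, `r_squared` (within-season
#'   regression) and `F`, `df`, `anova_p` (among-year one-way ANOVA; `NA`
#'   with a flag when degenerate).
#' @export
arthropod_trends <- function(samples) {
  stopifnot(is.data.frame(samples))
  if (!"abundance" %in% names(samples)) {
    if (any(samples$veg_mass_g <= 0)) stop("veg_mass_g must be positive", call. = FALSE)
    if (any(samples$count < 0)) stop("counts must be non-negative", call. = FALSE)
    samples$abundance <- samples$count / samples$veg_mass_g
  }
  if (nrow(samples) < 2L) stop("need at least two sampling sessions", call. = FALSE)
  fit <- stats::lm(abundance ~ day_of_year, data = samples)
  sm <- summary(fit)
  slope <- stats::coef(fit)[["day_of_year"]]
  slope_p <- if (nrow(sm$coefficients) > 1L && isTRUE(sm$sigma > 0)) {
    sm$coefficients["day_of_year", "Pr(>|t|)"]
  } else NA_real_
  out <- list(slope = slope, slope_p = slope_p, r_squared = sm$r.squared)
  if (stats::var(samples$abundance) < 1e-18) {
    out$slope <- 0
    out$F <- NA_real_; out$df <- c(NA, NA); out$anova_p <- NA_real_
    out$flag <- "constant abundance: trend and ANOVA undefined"
  } else if (length(unique(samples$year)) >= 2L) {
    av <- stats::anova(stats::aov(abundance ~ factor(year), data = samples))
    out$F <- av[["F value"]][1]
    out$df <- c(av$Df[1], av$Df[2])
    out$anova_p <- av[["Pr(>F)"]][1]
    if (!is.finite(out$F)) out$flag <- "degenerate ANOVA (zero residual variance)"
  } else {
    out$F <- NA_real_; out$df <- c(NA, NA); out$anova_p <- NA_real_
    out$flag <- "single year: among-year ANOVA not estimable"
  }
  out
}
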