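# Quantities derived from transient-aware CJS fits: expected stopover
# duration, transient probability, and model-averaged group estimates.

#' Expected stopover duration from daily persistence
#'
#' With constant daily site persistence `phi`, the expected remaining stay
#' is the expected-lifespan transform `-1 / ln(phi)` (days). The
#' delta-method standard error is `SE(phi) / (phi * ln(phi)^2)`.
#'
#' @param phi Daily persistence probability in (0, 1). Vectorised.
#' @param se Optional SE of `phi`.
#' @return Duration in days, or (with `se`) a list `duration`, `se`.
#' @export
expected_stopover_duration <- function(phi, se = NULL) {
  if (any(phi <= 0) || any(phi >= 1)) {
    stop("phi must lie strictly between 0 and 1", call. = FALSE)
  }
  d <- -1 / log(phi)
  if (is.null(se)) return(d)
  list(duration = d, se = se / (phi * log(phi)^2))
}

#' Transient probability from the two persistence classes
#'
#' The proportion of newly caught birds that depart on the day of arrival:
#' the first-interval persistence of all birds divided by the persistence
#' of birds already present, `tau = 1 - phi1 / phi2`, reported as a
#' percentage. The variance uses the delta method with gradient
#' `(-1/phi2, phi1/phi2^2)` and the fitted covariance of `(phi1, phi2)`.
#' Raw values outside [0, 100] are clamped with a flag.
#'
#' @param phi1 First-interval (all newly caught birds) daily persistence.
#' @param phi2 Subsequent-interval (resident) daily persistence in (0, 1].
#' @param vcov Optional 2x2 covariance matrix of `(phi1, phi2)` on the
#'   probability scale.
#' @return List with `percent`, `se` (NA without `vcov`), and `clamped`.
#' @export
transient_probability <- function(phi1, phi2, vcov = NULL) {
  if (phi2 <= 0) stop("phi2 must be positive", call. = FALSE)
  if (phi1 < 0) stop("phi1 must be non-negative", call. = FALSE)
  tau <- 1 - phi1 / phi2
  pct_raw <- 100 * tau
  clamped <- pct_raw < 0 || pct_raw > 100
  pct <- min(max(pct_raw, 0), 100)
  se <- NA_real_
  if (!is.null(vcov)) {
    g <- c(-1 / phi2, phi1 / phi2^2)
    se <- 100 * sqrt(drop(t(g) %*% vcov %*% g))
  }
  list(percent = pct, raw_percent = pct_raw, se = se, clamped = clamped)
}

# real-scale (phi1, phi2) estimates with covariance for one covariate row
cjs_phi_pair <- function(fit, newdata) {
  mm <- cjs_model_matrices(newdata, fit$formulas$phi1, fit$formulas$phi2,
                           fit$formulas$p, fit$xlevels)
  i1 <- seq_len(ncol(mm$X1))
  i2 <- ncol(mm$X1) + seq_len(ncol(mm$X2))
  eta1 <- drop(mm$X1[1, ] %*% fit$coef[i1])
  eta2 <- drop(mm$X2[1, ] %*% fit$coef[i2])
  p1 <- inv_logit(eta1); p2 <- inv_logit(eta2)
  J <- matrix(0, 2, length(fit$coef))
  J[1, i1] <- mm$X1[1, ] * p1 * (1 - p1)
  J[2, i2] <- mm$X2[1, ] * p2 * (1 - p2)
  V <- J %*% fit$vcov %*% t(J)
  list(phi = c(phi1 = p1, phi2 = p2), vcov = V)
}

#' CJS model selection and group stopover estimates
#'
#' Fits every candidate persistence structure (shared detection structure),
#' ranks by AICc, and derives model-averaged group estimates: per-group
#' real-scale phi1/phi2 (averaged over the competing set on the
#' probability scale, weights renormalised), expected stopover duration of
#' non-transients, and transient percentage, each with delta-method /
#' unconditional standard errors. Groups with a condition covariate are
#' evaluated at the group's mean condition.
#'
#' @param data Encounter-history data frame (`occ*` + covariates).
#' @param candidates Named list of candidate specs; each element is a list
#'   with formulas `phi1`, `phi2` (and optionally `p` to override
#'   `p_formula`).
#' @param p_formula Detection structure shared by all candidates
#'   (default `~1`).
#' @param group_vars Covariates defining the reporting groups (default
#'   those appearing in the candidate phi formulas, categorical only).
#' @param delta_max Competing-set threshold (default 4).
#' @param seed Seed forwarded to [fit_cjs()].
#' @return Object of class `stopover_fit`: `aic` (`aictab`), `estimates`
#'   (per-group duration and transient percent with SEs), `fits`.
#' @export
stopover_model_selection <- function(data, candidates, p_formula = ~1,
                                     group_vars = NULL, delta_max = 4,
                                     seed = 1L) {
  stopifnot(length(candidates) >= 1L)
  fits <- list()
  for (nm in names(candidates)) {
    cand <- candidates[[nm]]
    f <- try(fit_cjs(data, phi1 = cand$phi1 %||% ~1, phi2 = cand$phi2 %||% ~1,
                     p = cand$p %||% p_formula, seed = seed), silent = TRUE)
    if (!inherits(f, "try-error")) {
      f$label <- nm
      fits[[nm]] <- f
    }
  }
  if (length(fits) == 0L) stop("all candidate fits failed", call. = FALSE)
  tab <- aic_table(fits, delta_max = delta_max)

  if (is.null(group_vars)) {
    vars <- unique(unlist(lapply(fits, function(f) {
      c(all.vars(f$formulas$phi1), all.vars(f$formulas$phi2))
    })))
    group_vars <- vars[vapply(vars, function(v) !is.numeric(data[[v]]),
                              logical(1))]
  }
  est <- stopover_group_estimates(tab, data, group_vars)
  structure(list(aic = tab, estimates = est, fits = tab$fits,
                 group_vars = group_vars),
            class = "stopover_fit")
}

# model-averaged per-group estimates over the competing set
stopover_group_estimates <- function(tab, data, group_vars) {
  in_top <- top_set(tab)
  w <- tab$table$weight[in_top]
  w <- w / sum(w)
  fits <- tab$fits[in_top]

  cells <- list(overall = data)
  for (v in group_vars) {
    for (lv in unique(as.character(data[[v]]))) {
      cells[[paste(v, lv, sep = "=")]] <- data[data[[v]] == lv, , drop = FALSE]
    }
  }
  rows <- lapply(names(cells), function(cell) {
    sub <- cells[[cell]]
    # evaluate at the cell's modal factor levels and mean numeric covariates
    nd <- sub[1, , drop = FALSE]
    for (v in names(sub)) {
      if (grepl("^occ", v)) next
      if (is.numeric(sub[[v]])) {
        nd[[v]] <- mean(sub[[v]])
      } else {
        tb <- table(as.character(sub[[v]]))
        nd[[v]] <- names(tb)[which.max(tb)]
      }
    }
    phi1s <- numeric(length(fits)); phi2s <- numeric(length(fits))
    v11 <- numeric(length(fits)); v22 <- numeric(length(fits))
    v12 <- numeric(length(fits))
    for (i in seq_along(fits)) {
      pp <- cjs_phi_pair(fits[[i]], nd)
      phi1s[i] <- pp$phi[1]; phi2s[i] <- pp$phi[2]
      v11[i] <- pp$vcov[1, 1]; v22[i] <- pp$vcov[2, 2]; v12[i] <- pp$vcov[1, 2]
    }
    phi1 <- sum(w * phi1s); phi2 <- sum(w * phi2s)
    # unconditional variances on the probability scale
    var1 <- sum(w * (v11 + (phi1s - phi1)^2))
    var2 <- sum(w * (v22 + (phi2s - phi2)^2))
    cov12 <- sum(w * (v12 + (phi1s - phi1) * (phi2s - phi2)))
    V <- matrix(c(var1, cov12, cov12, var2), 2)
    dur <- expected_stopover_duration(phi2, sqrt(var2))
    tr <- transient_probability(phi1, phi2, V)
    data.frame(group = cell, n = nrow(sub),
               phi1 = phi1, phi1_se = sqrt(var1),
               phi2 = phi2, phi2_se = sqrt(var2),
               duration = dur$duration, duration_se = dur$se,
               transient_pct = tr$percent, transient_pct_se = tr$se,
               transient_clamped = tr$clamped,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stopover-duration change per unit migratory condition
#'
#' Analytic derivative of the expected-lifespan transform with respect to a
#' condition covariate entering logit(phi2):
#' `d duration / d condition = beta * (1 - phi2) / ln(phi2)^2`, evaluated
#' at the supplied persistence (e.g. at the group-mean condition).
#'
#' @param fit A `cjs` fit whose `phi2` formula contains `condition`.
#' @param phi2 Persistence at which to evaluate (default: fitted average).
#' @return Days per unit condition.
#' @export
condition_effect_days <- function(fit, phi2 = NULL) {
  cn <- "phi2:condition"
  if (!cn %in% names(fit$coef)) {
    stop("model has no condition effect on phi2", call. = FALSE)
  }
  if (is.null(phi2)) phi2 <- unname(predict(fit)["phi2", "estimate"])
  unname(fit$coef[cn]) * (1 - phi2) / log(phi2)^2
}

#' @export
print.stopover_fit <- function(x, ...) {
  cat("Transient-aware CJS stopover analysis\n")
  print(x$aic)
  cat("\nModel-averaged group estimates:\n")
  est <- x$estimates
  num <- vapply(est, is.numeric, logical(1))
  est[num] <- lapply(est[num], round, 3)
  print(est, row.names = FALSE)
  invisible(x)
}
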