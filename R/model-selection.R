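# AICc multimodel inference: candidate-set enumeration, Gaussian OLS fits,
# AICc, Akaike weights, model averaging with unconditional variances, and
# relative-importance weights.

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`, where `k` counts every
#' estimated parameter including the residual variance.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size; must exceed `k + 1`.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike differences and weights
#'
#' @param aicc_values Numeric vector of AICc values.
#' @return List with `delta` (differences from the minimum) and `weight`
#'   (`exp(-delta/2)` normalised to sum to one).
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) >= 1L)
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  list(delta = delta, weight = w / sum(w))
}

#' Enumerate a candidate model set
#'
#' All subsets of the main terms (including the empty/null model), each
#' augmented with every subset of the allowed interactions whose parent
#' mains are both present (interaction hierarchy). `always_include` terms
#' are appended to every non-null model.
#'
#' @param main_terms Character vector of main-effect terms.
#' @param interactions Character vector like `"A:B"`; parents must be in
#'   `main_terms`.
#' @param always_include Terms forced into every non-null model.
#' @return List of character vectors of terms; the null model is
#'   `character(0)`.
#' @export
enumerate_candidate_models <- function(main_terms, interactions = character(),
                                       always_include = character()) {
  stopifnot(!anyDuplicated(main_terms))
  for (ia in interactions) {
    parents <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (!all(parents %in% main_terms)) {
      stop("interaction references unknown main term: ", ia, call. = FALSE)
    }
  }
  n <- length(main_terms)
  specs <- list(character(0))
  for (m in seq_len(2^n - 1)) {
    mains <- main_terms[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
    ok_ints <- interactions[vapply(interactions, function(ia) {
      all(strsplit(ia, ":", fixed = TRUE)[[1]] %in% mains)
    }, logical(1))]
    ni <- length(ok_ints)
    for (s in seq_len(max(1L, 2^ni)) - 1L) {
      ints <- if (ni) ok_ints[bitwAnd(s, bitwShiftL(1L, seq_len(ni) - 1L)) != 0L]
              else character(0)
      specs[[length(specs) + 1L]] <- c(mains, ints)
    }
  }
  if (length(always_include)) {
    specs <- lapply(specs, function(tt) {
      if (length(tt) == 0L) tt else unique(c(always_include, tt))
    })
  }
  unique(specs)
}

spec_formula <- function(response, terms) {
  rhs <- if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
  stats::as.formula(paste(response, "~", rhs))
}

spec_label <- function(terms) {
  if (length(terms) == 0L) "null" else paste(terms, collapse = " + ")
}

#' Fit one Gaussian general linear model for AICc comparison
#'
#' Ordinary least squares via [stats::lm()]; the reported log-likelihood is
#' the Gaussian maximum-likelihood value (ML error variance), and `k`
#' counts the regression coefficients plus the residual variance, so AICc
#' values are comparable across fixed-effect structures.
#'
#' @param response Response column name.
#' @param terms Character vector of RHS terms (empty = intercept only).
#' @param data Data frame; factor reference levels are taken as already set.
#' @return Object of class `refuel_fit`: list with `terms`, `fit` (the lm),
#'   `coef`, `se`, `loglik`, `k`, `n`, `aicc`, `label`.
#' @export
fit_refuel_model <- function(response, terms, data) {
  f <- spec_formula(response, terms)
  fit <- stats::lm(f, data = data)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design for model: ", spec_label(terms), call. = FALSE)
  }
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit)) + 1L
  n <- stats::nobs(fit)
  sm <- summary(fit)
  structure(list(terms = terms, formula = f, fit = fit,
                 coef = stats::coef(fit),
                 se = sm$coefficients[, "Std. Error"],
                 loglik = ll, k = k, n = n,
                 aicc = aicc(ll, k, n),
                 label = spec_label(terms)),
            class = "refuel_fit")
}

#' @export
print.refuel_fit <- function(x, ...) {
  cat(sprintf("refuel_fit: %s  (k = %d, n = %d, AICc = %.2f)\n",
              x$label, x$k, x$n, x$aicc))
  invisible(x)
}

#' Build an AICc model-selection table
#'
#' @param fits List of fitted models, each with `aicc`, `k`, `loglik`,
#'   `label` and `terms` components (e.g. [fit_refuel_model()] or
#'   [fit_cjs()] results).
#' @param delta_max Threshold defining the top (competing) model set;
#'   default 4.
#' @return Object of class `aictab`: the ranked table (`data.frame`) plus
#'   the fits (in ranked order) and `delta_max`.
#' @export
aic_table <- function(fits, delta_max = 4) {
  stopifnot(length(fits) >= 1L)
  av <- vapply(fits, function(f) f$aicc, numeric(1))
  aw <- akaike_weights(av)
  ord <- order(av)
  tab <- data.frame(
    model = vapply(fits, function(f) f$label, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aicc = av, delta = aw$delta, weight = aw$weight,
    stringsAsFactors = FALSE)[ord, ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits[ord], delta_max = delta_max),
            class = "aictab")
}

#' @export
print.aictab <- function(x, n = 10, ...) {
  cat(sprintf("AICc model selection (%d candidates; top set: delta <= %g)\n",
              nrow(x$table), x$delta_max))
  tab <- utils::head(x$table, n)
  tab$loglik <- round(tab$loglik, 2)
  tab$aicc <- round(tab$aicc, 2)
  tab$delta <- round(tab$delta, 2)
  tab$weight <- round(tab$weight, 3)
  print(tab)
  invisible(x)
}

#' Models in the competing (top) set
#'
#' @param tab An `aictab`.
#' @return Logical vector over the ranked fits: `delta <= delta_max`.
#' @export
top_set <- function(tab) {
  stopifnot(inherits(tab, "aictab"))
  tab$table$delta <= tab$delta_max
}

#' Relative variable importance
#'
#' `w+(j)`: the sum of Akaike weights across all candidate models whose
#' term set contains variable `j` (not renormalised).
#'
#' @param tab An `aictab`.
#' @param term Term name as used in the model specs.
#' @return Scalar in `[0, 1]`.
#' @export
w_plus <- function(tab, term) {
  has <- vapply(tab$fits, function(f) term %in% f$terms, logical(1))
  sum(tab$table$weight[has])
}

#' Model-averaged coefficient with unconditional standard error
#'
#' Averages a coefficient across the models that contain it (by default
#' restricted to the competing set, `delta <= delta_max`), with weights
#' renormalised over those models. The unconditional standard error follows
#' Burnham & Anderson:
#' `SE = sum_i w_i * sqrt(SE_i^2 + (b_i - b_bar)^2)`.
#'
#' @param tab An `aictab` of `refuel_fit` objects.
#' @param coef_name Coefficient (design-matrix column) name.
#' @param subset `"top"` (competing set, default) or `"all"`.
#' @return List with `estimate`, `se` (unconditional), `n_models`, and
#'   `w_plus` (relative importance of the owning term over the full set).
#' @export
model_average <- function(tab, coef_name, subset = c("top", "all")) {
  subset <- match.arg(subset)
  in_set <- if (subset == "top") top_set(tab) else rep(TRUE, length(tab$fits))
  has <- vapply(tab$fits, function(f) coef_name %in% names(f$coef), logical(1))
  use <- which(in_set & has)
  if (length(use) == 0L) {
    stop("coefficient absent from all models in the set: ", coef_name,
         call. = FALSE)
  }
  w <- tab$table$weight[use]
  w <- w / sum(w)
  b <- vapply(tab$fits[use], function(f) unname(f$coef[coef_name]), numeric(1))
  s <- vapply(tab$fits[use], function(f) unname(f$se[coef_name]), numeric(1))
  bbar <- sum(w * b)
  se_u <- sum(w * sqrt(s^2 + (b - bbar)^2))
  term <- owning_term(tab, coef_name)
  list(estimate = bbar, se = se_u, n_models = length(use),
       w_plus = if (is.na(term)) NA_real_ else w_plus(tab, term))
}

# map a design-matrix coefficient name back to the model term that owns it
owning_term <- function(tab, coef_name) {
  if (coef_name %in% unlist(lapply(tab$fits, `[[`, "terms"))) return(coef_name)
  for (f in tab$fits) {
    if (is.null(f$fit)) next
    if (coef_name %in% names(f$coef)) {
      asn <- attr(stats::model.matrix(f$fit), "assign")
      tl <- attr(stats::terms(f$fit), "term.labels")
      j <- asn[match(coef_name, colnames(stats::model.matrix(f$fit)))]
      if (j == 0) return(NA_character_)
      return(tl[j])
    }
  }
  NA_character_
}
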