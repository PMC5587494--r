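# Plasma-metabolite refueling index: ln+1 transforms, metabolite
# correlation, and the covariance-PCA index.

#' ln(x + 1) transform for metabolite concentrations
#'
#' Applied to plasma triglyceride and beta-hydroxy-butyrate (and, where
#' requested, to bleed time) to satisfy normality assumptions.
#'
#' @param x Concentrations (mmol/L) or minutes; must exceed -1. Vectorised.
#' @return `log(x + 1)`.
#' @export
ln1p <- function(x) {
  if (any(x <= -1)) stop("ln+1 transform requires values > -1", call. = FALSE)
  log(x + 1)
}

#' Transform the metabolite columns of a plasma table
#'
#' @param plasma Data frame with `triglyceride` and `bohb` (mmol/L),
#'   optionally `bleedtime` (min).
#' @param transform_bleedtime Also ln+1 transform `bleedtime` into
#'   `ln_bleedtime`? Default TRUE.
#' @return `plasma` with added `ln_trig`, `ln_bohb` (and `ln_bleedtime`).
#' @export
transform_metabolites <- function(plasma, transform_bleedtime = TRUE) {
  stopifnot(all(c("triglyceride", "bohb") %in% names(plasma)))
  plasma$ln_trig <- ln1p(plasma$triglyceride)
  plasma$ln_bohb <- ln1p(plasma$bohb)
  if (transform_bleedtime && "bleedtime" %in% names(plasma)) {
    plasma$ln_bleedtime <- ln1p(plasma$bleedtime)
  }
  plasma
}

#' Correlation between transformed metabolite concentrations
#'
#' Pearson correlation of ln+1-transformed triglyceride and
#' beta-hydroxy-butyrate, with the exact t statistic
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` df.
#'
#' @param plasma Data frame (transformed columns added if absent).
#' @return List with `r`, `t`, `df`, `p`.
#' @export
metabolite_correlation <- function(plasma) {
  if (!all(c("ln_trig", "ln_bohb") %in% names(plasma))) {
    plasma <- transform_metabolites(plasma, transform_bleedtime = FALSE)
  }
  x <- plasma$ln_trig; y <- plasma$ln_bohb
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a metabolite column", call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  t <- if (abs(r) < 1) r * sqrt(df) / sqrt(1 - r^2) else sign(r) * Inf
  list(r = r, t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Refueling index: leading principal component of the transformed
#' metabolites
#'
#' Eigen-decomposition of the 2x2 covariance matrix of the centred
#' ln+1-transformed concentrations (covariance, not correlation, PCA: the
#' two metabolites are on a common ln-mmol/L scale and their unequal
#' variances are informative). Scores are projections on the leading
#' eigenvector, sign-fixed so the triglyceride loading is positive; larger
#' scores indicate faster fuel deposition. Scores average zero by
#' construction.
#'
#' @param plasma Data frame (transformed columns added if absent).
#' @return Object of class `refuel_index`: list with `scores` (named by
#'   `bird_id` when present), `loadings` (unit-norm, triglyceride first),
#'   `var_explained`, `eigenvalues`, `center`.
#' @export
refueling_index <- function(plasma) {
  if (!all(c("ln_trig", "ln_bohb") %in% names(plasma))) {
    plasma <- transform_metabolites(plasma, transform_bleedtime = FALSE)
  }
  X <- cbind(trig = plasma$ln_trig, bohb = plasma$ln_bohb)
  if (nrow(X) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (any(apply(X, 2, stats::var) == 0)) {
    stop("rank-deficient input: constant metabolite column", call. = FALSE)
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  S <- stats::cov(Xc)
  eig <- eigen(S, symmetric = TRUE)
  v <- eig$vectors[, 1]
  if (v[1] < 0) v <- -v       # sign convention: triglyceride loads positively
  scores <- as.numeric(Xc %*% v)
  if (!is.null(plasma$bird_id)) names(scores) <- plasma$bird_id
  structure(list(scores = scores,
                 loadings = stats::setNames(v, c("triglyceride", "bohb")),
                 var_explained = eig$values[1] / sum(eig$values),
                 eigenvalues = eig$values,
                 center = ctr),
            class = "refuel_index")
}

#' @export
print.refuel_index <- function(x, ...) {
  cat("Refueling index (covariance PCA of ln+1 metabolites)\n")
  cat(sprintf("  n = %d birds\n", length(x$scores)))
  cat(sprintf("  loadings: triglyceride %+0.3f, BOHB %+0.3f\n",
              x$loadings[1], x$loadings[2]))
  cat(sprintf("  PC1 variance explained: %.1f%%\n", 100 * x$var_explained))
  invisible(x)
}

#' Project new samples onto a fitted refueling index
#'
#' @param object A `refuel_index`.
#' @param newdata Plasma data frame.
#' @param ... Unused.
#' @return Numeric scores (centred with the fitting centre).
#' @export
predict.refuel_index <- function(object, newdata, ...) {
  if (!all(c("ln_trig", "ln_bohb") %in% names(newdata))) {
    newdata <- transform_metabolites(newdata, transform_bleedtime = FALSE)
  }
  Xc <- sweep(cbind(newdata$ln_trig, newdata$ln_bohb), 2, object$center)
  as.numeric(Xc %*% object$loadings)
}
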