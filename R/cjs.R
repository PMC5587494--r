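# Cormack-Jolly-Seber models with time-since-marking (transient) structure
# on collapsed encounter histories. All birds are released at occasion 1;
# daily persistence phi has two time-since-marking classes (first interval
# phi1, subsequent intervals phi2), each a logit-linear predictor over
# individual covariates; detection p is a logit-linear predictor (year
# grouping and/or covariates), constant over occasions within a bird. With
# no mortality assumed at the stopover site, "survival" is site
# persistence.

#' Collapse dated detections into fixed-length encounter histories
#'
#' Aligns each bird's first capture to occasion 1 and places subsequent
#' detections at day offsets 1..(n_occasions - 1); detections beyond the
#' final occasion are dropped with a warning.
#'
#' @param detections Data frame with `bird_id` and `day` (day-of-year of
#'   each detection; first capture = earliest day).
#' @param n_occasions Number of occasions (default 9, the longest observed
#'   span between detections of one individual).
#' @return Data frame: `bird_id` plus 0/1 columns `occ1..occN`
#'   (`occ1` always 1).
#' @export
collapse_histories <- function(detections, n_occasions = 9L) {
  stopifnot(all(c("bird_id", "day") %in% names(detections)), n_occasions >= 2L)
  ids <- unique(detections$bird_id)
  H <- matrix(0L, length(ids), n_occasions,
              dimnames = list(NULL, paste0("occ", seq_len(n_occasions))))
  dropped <- 0L
  for (i in seq_along(ids)) {
    d <- sort(unique(detections$day[detections$bird_id == ids[i]]))
    off <- d - d[1] + 1L
    over <- off > n_occasions
    dropped <- dropped + sum(over)
    H[i, off[!over]] <- 1L
  }
  if (dropped > 0L) {
    warning(sprintf("%d detection(s) beyond occasion %d dropped", dropped,
                    n_occasions), call. = FALSE)
  }
  data.frame(bird_id = ids, H, stringsAsFactors = FALSE)
}

history_matrix <- function(data) {
  occ <- grep("^occ[0-9]+$", names(data), value = TRUE)
  occ <- occ[order(as.integer(sub("occ", "", occ)))]
  H <- as.matrix(data[occ])
  storage.mode(H) <- "integer"
  if (any(H[, 1] != 1L)) stop("every history must start with a detection", call. = FALSE)
  H
}

#' Read MARK-style .inp encounter histories
#'
#' Parses lines of the form `/* id */ 110010000 1;` (comment with the bird
#' id, the 0/1 history string, a frequency, terminating semicolon).
#'
#' @param path File path.
#' @return Data frame with `bird_id` and `occ1..occN` columns (rows
#'   replicated by frequency).
#' @export
read_inp <- function(path) {
  lines <- grep(";", readLines(path), value = TRUE, fixed = TRUE)
  recs <- lapply(lines, function(l) {
    id <- if (grepl("/\\*", l)) trimws(sub(".*/\\*(.*?)\\*/.*", "\\1", l)) else NA
    body <- trimws(sub(";.*$", "", sub(".*\\*/", "", l)))
    parts <- strsplit(body, "\\s+")[[1]]
    hist <- parts[1]
    freq <- if (length(parts) > 1L) as.integer(parts[2]) else 1L
    list(id = id, hist = hist, freq = freq)
  })
  nocc <- nchar(recs[[1]]$hist)
  rows <- do.call(rbind, lapply(recs, function(r) {
    h <- as.integer(strsplit(r$hist, "")[[1]])
    do.call(rbind, replicate(r$freq, h, simplify = FALSE))
  }))
  ids <- unlist(lapply(recs, function(r) rep(r$id, r$freq)))
  out <- data.frame(bird_id = ids, rows, stringsAsFactors = FALSE)
  names(out) <- c("bird_id", paste0("occ", seq_len(nocc)))
  out
}

#' Write encounter histories in MARK .inp dialect
#'
#' @param data Data frame with `bird_id` and `occ*` columns.
#' @param path Output path.
#' @export
write_inp <- function(data, path) {
  H <- history_matrix(data)
  lines <- sprintf("/* %s */ %s 1;", data$bird_id,
                   apply(H, 1, paste, collapse = ""))
  writeLines(lines, path)
  invisible(path)
}

# build per-bird (phi1, phi2, p) from parameters and model matrices
cjs_real_params <- function(params, mm) {
  i1 <- seq_len(ncol(mm$X1))
  i2 <- ncol(mm$X1) + seq_len(ncol(mm$X2))
  ip <- ncol(mm$X1) + ncol(mm$X2) + seq_len(ncol(mm$Xp))
  list(phi1 = inv_logit(drop(mm$X1 %*% params[i1])),
       phi2 = inv_logit(drop(mm$X2 %*% params[i2])),
       p = inv_logit(drop(mm$Xp %*% params[ip])))
}

cjs_model_matrices <- function(data, phi1, phi2, p, xlev = NULL) {
  if (!is.null(xlev)) {
    for (nm in intersect(names(xlev), names(data))) {
      data[[nm]] <- factor(data[[nm]], levels = xlev[[nm]])
    }
  }
  list(X1 = stats::model.matrix(phi1, data),
       X2 = stats::model.matrix(phi2, data),
       Xp = stats::model.matrix(p, data))
}

# factor levels of every categorical covariate a set of formulas touches
cjs_xlevels <- function(data, formulas) {
  vars <- unique(unlist(lapply(formulas, all.vars)))
  vars <- intersect(vars, names(data))
  xlev <- list()
  for (v in vars) {
    if (is.character(data[[v]]) || is.factor(data[[v]])) {
      xlev[[v]] <- levels(factor(data[[v]]))
    }
  }
  xlev
}

#' Negative log-likelihood of the transient CJS model
#'
#' Standard CJS likelihood conditional on first capture, with the
#' chi-recursion for never-seen-again tails:
#' `chi_K = 1`, `chi_t = (1 - phi_t) + phi_t (1 - p) chi_{t+1}`,
#' where `phi_t` is `phi1` for the first interval after release and `phi2`
#' thereafter.
#'
#' @param params Parameter vector on the logit scale, ordered
#'   (phi1 coefficients, phi2 coefficients, p coefficients).
#' @param data Data frame with `occ*` history columns plus any covariates.
#' @param phi1,phi2,p One-sided formulas for the three linear predictors.
#' @return The negative log-likelihood (`Inf` if non-finite terms arise).
#' @export
cjs_neg_loglik <- function(params, data, phi1 = ~1, phi2 = ~1, p = ~1) {
  if (any(!is.finite(params))) stop("non-finite parameters", call. = FALSE)
  H <- history_matrix(data)
  mm <- cjs_model_matrices(data, phi1, phi2, p)
  -sum(cjs_loglik_vec(params, H, mm))
}

# per-bird log-likelihood contributions, vectorised over birds
cjs_loglik_vec <- function(params, H, mm, last = NULL) {
  K <- ncol(H)
  n <- nrow(H)
  rp <- cjs_real_params(params, mm)
  phi1 <- rep_len(rp$phi1, n); phi2 <- rep_len(rp$phi2, n)
  p <- rep_len(rp$p, n)
  # chi[, t]: P(never detected after occasion t | alive at t)
  chi <- matrix(1, n, K)
  for (t in (K - 1):1) {
    phi_t <- if (t == 1L) phi1 else phi2
    chi[, t] <- (1 - phi_t) + phi_t * (1 - p) * chi[, t + 1]
  }
  if (is.null(last)) last <- apply(H, 1, function(h) max(which(h == 1L)))
  ll <- numeric(n)
  for (t in seq_len(K - 1)) {
    act <- t < last                      # interval t -> t+1 inside the history
    phi_t <- if (t == 1L) phi1 else phi2
    det <- H[, t + 1] == 1L
    ll <- ll + ifelse(act, log(phi_t) + ifelse(det, log(p), log(1 - p)), 0)
  }
  ll + log(chi[cbind(seq_len(n), last)])
}

#' Fit a transient-aware CJS model
#'
#' Maximises the conditional-on-first-capture likelihood on the logit scale
#' by quasi-Newton optimisation from multiple seeded starts; standard
#' errors come from the inverse of the numerically differentiated observed
#' Hessian. The AICc sample size is the number of released individuals.
#'
#' @param data Data frame with `occ*` history columns plus covariates.
#' @param phi1 Formula for first-interval persistence (time-since-marking
#'   class 1).
#' @param phi2 Formula for subsequent-interval persistence.
#' @param p Formula for detection (e.g. `~ year_group` for a
#'   first-year-vs-later detection difference).
#' @param n_starts Number of random restarts (default 5).
#' @param seed Seed for the restart draws.
#' @param control Passed to [stats::optim()] (method BFGS).
#' @return Object of class `cjs`: MLEs (`coef`, logit scale), `vcov`,
#'   `loglik`, `k`, `n`, `aicc`, real-scale parameter summaries (`real`),
#'   formulas, convergence info, `label`, `terms`.
#' @export
fit_cjs <- function(data, phi1 = ~1, phi2 = ~1, p = ~1, n_starts = 5L,
                    seed = 1L, control = list(maxit = 500, reltol = 1e-10)) {
  H <- history_matrix(data)
  xlev <- cjs_xlevels(data, list(phi1, phi2, p))
  mm <- cjs_model_matrices(data, phi1, phi2, p, xlev)
  npar <- ncol(mm$X1) + ncol(mm$X2) + ncol(mm$Xp)
  last <- apply(H, 1, function(h) max(which(h == 1L)))
  nll <- function(par) {
    v <- -sum(cjs_loglik_vec(par, H, mm, last))
    if (!is.finite(v)) 1e10 else v
  }
  set.seed(substream_seed(seed, "cjs-starts"))
  starts <- rbind(rep(0, npar),
                  matrix(stats::rnorm((n_starts - 1L) * npar, 0, 1),
                         ncol = npar))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    op <- try(stats::optim(starts[s, ], nll, method = "BFGS",
                           control = control), silent = TRUE)
    if (inherits(op, "try-error")) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("CJS fit failed from all starts", call. = FALSE)
  hess <- stats::optimHess(best$par, nll)
  vc <- try(solve(hess), silent = TRUE)
  singular <- inherits(vc, "try-error") || any(!is.finite(vc)) ||
    any(diag(as.matrix(vc)) < 0)
  if (singular) {
    warning("singular Hessian: standard errors unavailable", call. = FALSE)
    vc <- matrix(NA_real_, npar, npar)
  }
  cn <- c(paste0("phi1:", colnames(mm$X1)), paste0("phi2:", colnames(mm$X2)),
          paste0("p:", colnames(mm$Xp)))
  dimnames(vc) <- list(cn, cn)
  est <- stats::setNames(best$par, cn)
  n <- nrow(H)
  ll <- -best$value
  k <- npar
  term_lab <- function(f) attr(stats::terms(f), "term.labels")
  fml_lab <- function(f) {
    tl <- term_lab(f)
    if (length(tl)) paste(tl, collapse = "+") else "1"
  }
  label <- sprintf("phi1(%s) phi2(%s) p(%s)",
                   fml_lab(phi1), fml_lab(phi2), fml_lab(p))
  structure(list(coef = est, vcov = vc, loglik = ll, k = k, n = n,
                 aicc = aicc(ll, k, n),
                 formulas = list(phi1 = phi1, phi2 = phi2, p = p),
                 data = data, mm = mm, xlevels = xlev,
                 convergence = best$convergence, singular = singular,
                 label = label,
                 terms = unique(c(term_lab(phi1), term_lab(phi2)))),
            class = "cjs")
}

#' @export
print.cjs <- function(x, ...) {
  cat("Transient-aware CJS model:", x$label, "\n")
  cat(sprintf("  n released = %d, logLik = %.3f, k = %d, AICc = %.2f\n",
              x$n, x$loglik, x$k, x$aicc))
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = x$coef, se = se), 4))
  invisible(x)
}

#' @export
coef.cjs <- function(object, ...) object$coef

#' @export
vcov.cjs <- function(object, ...) object$vcov

#' @export
logLik.cjs <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
summary.cjs <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coef / se
  tab <- cbind(estimate = object$coef, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  out <- list(label = object$label, coefficients = tab,
              real = predict(object), loglik = object$loglik,
              k = object$k, n = object$n, aicc = object$aicc)
  class(out) <- "summary.cjs"
  out
}

#' @export
print.summary.cjs <- function(x, ...) {
  cat("Transient-aware CJS model:", x$label, "\n\nLogit-scale coefficients:\n")
  print(round(x$coefficients, 4))
  cat("\nReal-scale parameters (at observed covariates, averaged):\n")
  print(round(x$real, 4))
  cat(sprintf("\nlogLik = %.3f, k = %d, n = %d, AICc = %.2f\n",
              x$loglik, x$k, x$n, x$aicc))
  invisible(x)
}

#' Real-scale parameter estimates from a CJS fit
#'
#' Evaluates phi1, phi2 and p on the probability scale for `newdata` (or
#' the fitting data), with delta-method standard errors.
#'
#' @param object A `cjs` fit.
#' @param newdata Optional data frame of covariates.
#' @param average Average over rows (default TRUE), giving one row per
#'   parameter; otherwise per-row estimates are returned as a list.
#' @param ... Unused.
#' @return With `average = TRUE`, a matrix with rows phi1/phi2/p and
#'   columns estimate/se.
#' @export
predict.cjs <- function(object, newdata = NULL, average = TRUE, ...) {
  data <- newdata %||% object$data
  mm <- cjs_model_matrices(data, object$formulas$phi1, object$formulas$phi2,
                           object$formulas$p, object$xlevels)
  i1 <- seq_len(ncol(mm$X1))
  i2 <- ncol(mm$X1) + seq_len(ncol(mm$X2))
  ip <- ncol(mm$X1) + ncol(mm$X2) + seq_len(ncol(mm$Xp))
  blocks <- list(phi1 = list(X = mm$X1, idx = i1),
                 phi2 = list(X = mm$X2, idx = i2),
                 p = list(X = mm$Xp, idx = ip))
  res <- lapply(blocks, function(b) {
    eta <- drop(b$X %*% object$coef[b$idx])
    prob <- inv_logit(eta)
    V <- object$vcov[b$idx, b$idx, drop = FALSE]
    se <- vapply(seq_along(eta), function(i) {
      g <- b$X[i, ] * prob[i] * (1 - prob[i])   # d prob / d beta
      sqrt(drop(t(g) %*% V %*% g))
    }, numeric(1))
    cbind(estimate = prob, se = se)
  })
  if (!average) return(res)
  t(vapply(res, function(m) c(estimate = mean(m[, "estimate"]),
                              se = mean(m[, "se"])), numeric(2)))
}

#' Simulate encounter histories from a fitted CJS model
#'
#' Parametric simulation used e.g. for bootstrap standard errors: each
#' released bird persists through the first interval with its fitted phi1
#' and subsequent intervals with phi2, and is detected while present with
#' its fitted p.
#'
#' @param object A `cjs` fit.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of data frames shaped like the fitting data.
#' @export
simulate.cjs <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  H <- history_matrix(object$data)
  K <- ncol(H); n <- nrow(H)
  rp <- cjs_real_params(object$coef, object$mm)
  phi1 <- rep_len(rp$phi1, n); phi2 <- rep_len(rp$phi2, n)
  p <- rep_len(rp$p, n)
  lapply(seq_len(nsim), function(s) {
    alive <- rep(TRUE, n)
    Hs <- matrix(0L, n, K); Hs[, 1] <- 1L
    for (t in 2:K) {
      phi_t <- if (t == 2L) phi1 else phi2
      alive <- alive & (stats::runif(n) < phi_t)
      Hs[, t] <- as.integer(alive & (stats::runif(n) < p))
    }
    out <- object$data
    out[, paste0("occ", seq_len(K))] <- Hs
    out
  })
}
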