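# Feather-to-precipitation calibration and probabilistic breeding-destination
# assignment from stable-hydrogen isotope values.

# Calibration for non-ground-foraging Nearctic-Neotropical migrants:
#   d2Hf = 0.95 * d2Hp - 17.57
CAL_SLOPE <- 0.95
CAL_INTERCEPT <- -17.57

#' Default breeding-destination windows (precipitation scale)
#'
#' Two disjoint delta-2H windows of growing-season precipitation defining a
#' short-distance (southeastern U.S.) and a long-distance (boreal forest of
#' Canada) breeding destination.
#'
#' @return Named list of length-2 numeric ranges (per-mil vs VSMOW).
#' @export
default_destinations <- function() {
  list(southeast = c(-50, -10), boreal = c(-130, -70))
}

#' Convert a feather isotope value to its precipitation equivalent
#'
#' Inverts the feather calibration `d2Hf = 0.95 * d2Hp - 17.57`.
#'
#' @param d2h_f Feather delta-2H (per-mil vs VSMOW). Vectorised.
#' @param slope,intercept Calibration coefficients.
#' @return Precipitation-equivalent delta-2H.
#' @export
#' @examples
#' feather_to_precip(-65.07)  # -50
feather_to_precip <- function(d2h_f, slope = CAL_SLOPE, intercept = CAL_INTERCEPT) {
  stop_if_not_finite(d2h_f, "d2h_f")
  (d2h_f - intercept) / slope
}

#' Convert a precipitation isotope value to the feather scale
#'
#' @param d2h_p Precipitation delta-2H (per-mil vs VSMOW). Vectorised.
#' @inheritParams feather_to_precip
#' @return Feather-scale delta-2H.
#' @export
precip_to_feather <- function(d2h_p, slope = CAL_SLOPE, intercept = CAL_INTERCEPT) {
  stop_if_not_finite(d2h_p, "d2h_p")
  slope * d2h_p + intercept
}

check_windows_disjoint <- function(regions) {
  if (length(regions) < 2L) return(invisible(TRUE))
  rs <- lapply(regions, function(w) sort(range(w)))
  ord <- order(vapply(rs, `[`, numeric(1), 1L))
  rs <- rs[ord]
  for (i in seq_len(length(rs) - 1L)) {
    if (rs[[i + 1L]][1] < rs[[i]][2]) {
      stop("destination windows overlap: configuration error", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Monte-Carlo probability of origin for one feather value
#'
#' Draws `n_draws` values from a normal distribution centred on the observed
#' feather value (SD = `error_sd`, the combined measurement and calibration
#' error on the feather scale), converts each draw to the precipitation
#' scale, and returns the fraction of draws falling inside each destination
#' window.
#'
#' @param d2h_f Observed feather delta-2H (scalar, per-mil).
#' @param regions Named list of precipitation-scale windows
#'   (each a length-2 numeric range); defaults to [default_destinations()].
#' @param error_sd Error SD on the feather scale (per-mil); default 5.5.
#' @param n_draws Number of Monte-Carlo draws; default 1000.
#' @param seed Optional integer seed for the draws.
#' @return Named numeric vector of window probabilities (may sum to < 1:
#'   mass falling between or outside windows is unassigned).
#' @export
region_probability <- function(d2h_f, regions = default_destinations(),
                               error_sd = 5.5, n_draws = 1000L, seed = NULL) {
  stopifnot(length(d2h_f) == 1L, n_draws >= 1L)
  stop_if_not_finite(d2h_f, "d2h_f")
  if (error_sd <= 0) stop("error_sd must be positive", call. = FALSE)
  check_windows_disjoint(regions)
  if (!is.null(seed)) set.seed(seed)
  draws_p <- feather_to_precip(stats::rnorm(n_draws, mean = d2h_f, sd = error_sd))
  vapply(regions, function(w) {
    w <- sort(range(w))
    mean(draws_p >= w[1] & draws_p <= w[2])
  }, numeric(1))
}

# closed-form counterpart of region_probability (normal CDF on the feather
# scale); used as an analytic cross-check
region_probability_analytic <- function(d2h_f, regions = default_destinations(),
                                        error_sd = 5.5) {
  vapply(regions, function(w) {
    wf <- sort(precip_to_feather(sort(range(w))))
    stats::pnorm(wf[2], d2h_f, error_sd) - stats::pnorm(wf[1], d2h_f, error_sd)
  }, numeric(1))
}

#' Classify a bird's breeding destination
#'
#' Default rule: window membership of the point-estimate precipitation
#' equivalent (values in the gap between windows or outside all windows are
#' `"unassigned"`). Alternative rule `"max_prob"`: the window with the
#' largest Monte-Carlo probability, provided it exceeds `threshold`.
#'
#' @param d2h_p_equiv Precipitation-equivalent delta-2H (scalar).
#' @param regions Named list of windows; see [region_probability()].
#' @param rule `"window"` (default) or `"max_prob"`.
#' @param region_probs Named probabilities (required for `"max_prob"`).
#' @param threshold Minimum probability for `"max_prob"` assignment.
#' @return A destination label or `"unassigned"`.
#' @export
classify_destination <- function(d2h_p_equiv, regions = default_destinations(),
                                 rule = c("window", "max_prob"),
                                 region_probs = NULL, threshold = 0.5) {
  rule <- match.arg(rule)
  if (rule == "window") {
    for (lab in names(regions)) {
      w <- sort(range(regions[[lab]]))
      if (d2h_p_equiv >= w[1] && d2h_p_equiv <= w[2]) return(lab)
    }
    return("unassigned")
  }
  stopifnot(!is.null(region_probs))
  best <- which.max(region_probs)
  if (region_probs[best] >= threshold) names(region_probs)[best] else "unassigned"
}

#' Assign breeding destinations to a table of feather samples
#'
#' Vectorised front end combining [feather_to_precip()],
#' [region_probability()] and [classify_destination()].
#'
#' @param feathers Data frame with columns `bird_id` and `d2h_f`.
#' @param regions Named list of precipitation-scale windows.
#' @param error_sd Feather-scale error SD (per-mil).
#' @param n_draws Monte-Carlo draws per bird.
#' @param seed Integer seed (one substream per bird, derived).
#' @param rule Assignment rule passed to [classify_destination()].
#' @param plausible Feather-scale plausibility bounds; values outside
#'   trigger a warning.
#' @return Data frame: `bird_id`, `d2h_f`, `d2h_p_equiv`, one probability
#'   column per region (`p_<label>`), `destination`, `n_draws`.
#' @export
assign_destinations <- function(feathers, regions = default_destinations(),
                                error_sd = 5.5, n_draws = 1000L, seed = 1L,
                                rule = "window", plausible = c(-250, 50)) {
  stopifnot(is.data.frame(feathers), all(c("bird_id", "d2h_f") %in% names(feathers)))
  check_windows_disjoint(regions)
  if (any(feathers$d2h_f < plausible[1] | feathers$d2h_f > plausible[2])) {
    warning("feather d2H values outside plausibility bounds", call. = FALSE)
  }
  n <- nrow(feathers)
  probs <- matrix(NA_real_, n, length(regions),
                  dimnames = list(NULL, paste0("p_", names(regions))))
  dest <- character(n)
  d2h_p <- feather_to_precip(feathers$d2h_f)
  set.seed(substream_seed(seed, "assign"))
  seeds <- sample.int(2147483646L, n)
  for (i in seq_len(n)) {
    pr <- region_probability(feathers$d2h_f[i], regions, error_sd, n_draws,
                             seed = seeds[i])
    probs[i, ] <- pr
    dest[i] <- classify_destination(d2h_p[i], regions, rule = rule,
                                    region_probs = pr)
  }
  out <- data.frame(bird_id = feathers$bird_id, d2h_f = feathers$d2h_f,
                    d2h_p_equiv = d2h_p, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(probs))
  out$destination <- dest
  out$n_draws <- n_draws
  out
}
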