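logit <- function(p) log(p / (1 - p))

hist_df <- function(...) {
  H <- rbind(...)
  out <- as.data.frame(H)
  names(out) <- paste0("occ", seq_len(ncol(H)))
  out
}

test_that("dated detections collapse onto day-1-aligned histories", {
  d <- data.frame(bird_id = c("a", "b", "b", "b"), day = c(100, 100, 101, 103))
  h <- collapse_histories(d, n_occasions = 9)
  expect_equal(unname(unlist(h[h$bird_id == "a", -1])), c(1, rep(0, 8)))
  expect_equal(unname(unlist(h[h$bird_id == "b", -1])),
               c(1, 1, 0, 1, 0, 0, 0, 0, 0))
  # a detection beyond the final occasion is dropped with a warning
  d2 <- data.frame(bird_id = "c", day = c(100, 120))
  expect_warning(h2 <- collapse_histories(d2, 9), "dropped")
  expect_equal(sum(h2[, -1]), 1)
})

test_that("MARK .inp files round-trip", {
  h <- hist_df(c(1, 1, 0, 0, 1), c(1, 0, 0, 0, 0))
  h <- cbind(bird_id = c("x1", "x2"), h)
  path <- withr::local_tempfile(fileext = ".inp")
  write_inp(h, path)
  expect_match(readLines(path)[1], "/\\* x1 \\*/ 11001 1;")
  h2 <- read_inp(path)
  expect_equal(h2, h, ignore_attr = TRUE)
})

test_that("CJS likelihood matches hand products on short histories", {
  par <- c(logit(0.5), logit(0.5), logit(0.5))
  expect_equal(cjs_neg_loglik(par, hist_df(c(1, 1))), -log(0.25),
               tolerance = 1e-12)
  expect_equal(cjs_neg_loglik(par, hist_df(c(1, 0))), -log(0.75),
               tolerance = 1e-12)
  par3 <- c(logit(0.6), logit(0.6), logit(0.5))
  expect_equal(cjs_neg_loglik(par3, hist_df(c(1, 0, 1))), -log(0.09),
               tolerance = 1e-12)
  # additivity over birds
  both <- hist_df(c(1, 1), c(1, 0))
  expect_equal(cjs_neg_loglik(par, both), -log(0.25) - log(0.75),
               tolerance = 1e-12)
  expect_error(cjs_neg_loglik(c(NA, 0, 0), hist_df(c(1, 1))), "non-finite")
  expect_error(cjs_neg_loglik(par, hist_df(c(0, 1))), "start with a detection")
})

test_that("outcome probabilities sum to one over all enumerable histories", {
  set.seed(31)
  for (K in 2:4) {
    H <- all_histories(K)
    for (rep in 1:3) {
      par <- c(rnorm(1), rnorm(1), rnorm(1))
      total <- sum(vapply(seq_len(nrow(H)), function(i) {
        d <- as.data.frame(H)[i, , drop = FALSE]
        exp(-cjs_neg_loglik(par, d))
      }, numeric(1)))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
})

test_that("likelihood agrees with a brute-force latent-state enumeration", {
  phi1 <- 0.45; phi2 <- 0.8; p <- 0.35
  par <- c(logit(phi1), logit(phi2), logit(p))
  H <- all_histories(3)
  for (i in seq_len(nrow(H))) {
    d <- as.data.frame(H)[i, , drop = FALSE]
    expect_equal(exp(-cjs_neg_loglik(par, d)),
                 brute_cjs_prob(unlist(H[i, ]), phi1, phi2, p),
                 tolerance = 1e-12)
  }
})

test_that("the transient CJS fit recovers generating parameters", {
  truth <- c(phi1 = 0.35, phi2 = 0.75, p = 0.4)
  h <- sim_histories(800, tau = 1 - truth["phi1"] / truth["phi2"],
                     phi = truth["phi2"], p = truth["p"],
                     n_occasions = 9, seed = 21)
  fit <- fit_cjs(h, seed = 2)
  est <- predict(fit)
  for (par in rownames(est)) {
    expect_lt(abs(est[par, "estimate"] - truth[par]), 2 * est[par, "se"])
  }
  # vcov is symmetric with positive diagonal
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-8)
  expect_true(all(diag(fit$vcov) > 0))
  # logLik method carries df and n
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 3)
  expect_equal(attr(ll, "nobs"), 800)
})

test_that("covariate effects on persistence are recovered", {
  set.seed(77)
  n <- 1000
  x <- rnorm(n)
  phi2 <- plogis(1 + 0.8 * x)
  h <- sim_histories(n, tau = 0.3, phi = phi2, p = 0.5, n_occasions = 7,
                     seed = 13)
  h$x <- x
  fit <- fit_cjs(h, phi1 = ~1, phi2 = ~x, p = ~1, seed = 3)
  b <- coef(fit)["phi2:x"]
  se <- sqrt(diag(vcov(fit))["phi2:x"])
  expect_lt(abs(b - 0.8), 2.5 * se)
})

test_that("parametric simulation from a fit matches its own parameters", {
  h <- sim_histories(600, tau = 0.4, phi = 0.7, p = 0.6, n_occasions = 6,
                     seed = 5)
  fit <- fit_cjs(h, seed = 4)
  sims <- simulate(fit, nsim = 30, seed = 99)
  # apparent first-interval persistence*detection: mean occ2 detection rate
  p2 <- mean(vapply(sims, function(s) mean(s$occ2), numeric(1)))
  rp <- predict(fit)
  expect_equal(p2, rp["phi1", "estimate"] * rp["p", "estimate"],
               tolerance = 0.03)
})
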