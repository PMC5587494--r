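test_that("AICc and Akaike weights reproduce closed-form values", {
  expect_equal(aicc(-50, 3, 20), 107.5)
  expect_error(aicc(-50, 19, 20), "n must exceed")
  # the small-sample correction vanishes as n grows
  expect_equal(aicc(-50, 3, 1e8), -2 * -50 + 2 * 3, tolerance = 1e-5)
  # boundary algebra: at k = n - 2 the correction equals 2k(k+1)
  k <- 5; n <- k + 2
  expect_equal(aicc(0, k, n) - 2 * k, 2 * k * (k + 1))

  aw <- akaike_weights(c(100, 102))
  expect_equal(aw$weight, c(0.7311, 0.2689), tolerance = 1e-4)
  aw3 <- akaike_weights(c(10, 12, 14))
  expect_equal(aw3$weight, c(0.6652, 0.2447, 0.0900), tolerance = 1e-3)
  # oracle: normalised {1, e^-1, e^-2}
  expect_equal(aw3$weight, exp(-(0:2)) / sum(exp(-(0:2))), tolerance = 1e-12)
  expect_equal(akaike_weights(5)$weight, 1)
  # invariants: weights sum to one, best model has delta zero
  set.seed(2)
  vals <- runif(20, 100, 140)
  aw4 <- akaike_weights(vals)
  expect_equal(sum(aw4$weight), 1, tolerance = 1e-12)
  expect_equal(min(aw4$delta), 0)
})

test_that("candidate enumeration respects the interaction hierarchy", {
  # four mains, no interactions: 15 models plus the null
  specs <- enumerate_candidate_models(c("A", "B", "C", "D"))
  expect_length(specs, 16)
  expect_true(any(vapply(specs, length, 1L) == 0))
  # one main
  expect_length(enumerate_candidate_models("A"), 2)
  # two mains and their interaction: null, A, B, A+B, A+B+A:B
  s2 <- enumerate_candidate_models(c("A", "B"), "A:B")
  expect_length(s2, 5)
  expect_false(any(vapply(s2, function(x) "A:B" %in% x && !all(c("A", "B") %in% x),
                          logical(1))))
  # the default biological tier enumerates exactly 144 candidates
  tiers <- default_refuel_tiers()
  s3 <- enumerate_candidate_models(tiers$tier2_terms, tiers$tier2_interactions,
                                   always_include = "ln_bleedtime")
  expect_length(s3, 144)
  # always_include appears in every non-null model and not in the null
  nonnull <- s3[vapply(s3, length, 1L) > 0]
  expect_true(all(vapply(nonnull, function(x) "ln_bleedtime" %in% x, logical(1))))
  expect_error(enumerate_candidate_models("A", "A:B"), "unknown main")
})

test_that("OLS fits match the normal-equations oracle", {
  d <- data.frame(x = c(1, 2, 3, 4, 5), y = c(1.1, 2.3, 2.8, 4.2, 4.9))
  f <- fit_refuel_model("y", "x", d)
  X <- cbind(1, d$x)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(f$coef), drop(beta), tolerance = 1e-8)
  # intercept-only model estimates the sample mean
  f0 <- fit_refuel_model("y", character(0), d)
  expect_equal(unname(f0$coef), mean(d$y))
  expect_equal(f0$label, "null")
  # exact linear data: slope recovered exactly
  d2 <- data.frame(x = 1:6, y = 2 * (1:6))
  f2 <- suppressWarnings(fit_refuel_model("y", "x", d2))
  expect_equal(unname(f2$coef["x"]), 2)
  # k counts coefficients plus the residual variance
  expect_equal(f$k, 3)
  expect_equal(f$aicc, aicc(f$loglik, 3, 5))
  # random small designs against the oracle
  set.seed(11)
  for (i in 1:5) {
    dd <- data.frame(a = rnorm(12), b = rnorm(12), y = rnorm(12))
    ff <- fit_refuel_model("y", c("a", "b"), dd)
    Xd <- cbind(1, dd$a, dd$b)
    expect_equal(unname(ff$coef), drop(solve(t(Xd) %*% Xd, t(Xd) %*% dd$y)),
                 tolerance = 1e-8)
  }
})

fake_fit <- function(label, terms, coef, se, aicc) {
  structure(list(terms = terms, coef = coef, se = se, loglik = NA_real_,
                 k = length(coef) + 1, n = 20, aicc = aicc, label = label),
            class = "refuel_fit")
}

test_that("model averaging follows the unconditional-variance formula", {
  # two models with weights 0.6 / 0.4: delta2 = 2 ln(1.5)
  f1 <- fake_fit("m1", "x", c(x = 1.0), c(x = 0.2), 100)
  f2 <- fake_fit("m2", "x", c(x = 1.5), c(x = 0.3), 100 + 2 * log(1.5))
  tab <- aic_table(list(f1, f2))
  expect_equal(tab$table$weight, c(0.6, 0.4), tolerance = 1e-12)
  ma <- model_average(tab, "x", subset = "all")
  expect_equal(ma$estimate, 1.2, tolerance = 1e-12)
  expect_equal(ma$se, 0.6 * sqrt(0.04 + 0.04) + 0.4 * sqrt(0.09 + 0.09),
               tolerance = 1e-12)
  expect_equal(ma$se, 0.3394, tolerance = 1e-4)

  # identical estimates everywhere: averaging changes nothing
  f3 <- fake_fit("m3", "x", c(x = 1.0), c(x = 0.2), 101)
  tab2 <- aic_table(list(f1, f3))
  ma2 <- model_average(tab2, "x", subset = "all")
  expect_equal(ma2$estimate, 1.0)
  expect_equal(ma2$se, 0.2)

  # a term present in every model has relative importance 1
  expect_equal(w_plus(tab, "x"), 1, tolerance = 1e-12)
  f4 <- fake_fit("null", character(0), c(`(Intercept)` = 0),
                 c(`(Intercept)` = 1), 99)
  tab3 <- aic_table(list(f1, f2, f4))
  expect_lt(w_plus(tab3, "x"), 1)
  expect_error(model_average(tab, "absent"), "absent from all models")
})
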