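test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 11)
  expect_identical(sim_birds(cfg), sim_birds(cfg))
  expect_identical(sim_isotope_samples(cfg, 50), sim_isotope_samples(cfg, 50))
  b <- sim_birds(cfg)
  expect_identical(sim_metabolites(cfg, b), sim_metabolites(cfg, b))
  expect_identical(sim_capture_histories(cfg, b), sim_capture_histories(cfg, b))
  # different seeds diverge
  expect_false(identical(sim_birds(cfg), sim_birds(sim_config(seed = 12))))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(destinations = list(
    a = list(window = c(-50, -10), arrival_mean = c(early = 1, middle = 2, late = 3),
             arrival_sd = 1, tau = 0.5, phi = 0.5),
    b = list(window = c(-20, 0), arrival_mean = c(early = 1, middle = 2, late = 3),
             arrival_sd = 1, tau = 0.5, phi = 0.5))), "overlap")
  expect_error(sim_config(p_detect = c(0.5, 1.2, 0.5, 0.5)), "detection")
  expect_error(sim_config(metabolites = modifyList(
    eval(formals(sim_config)$metabolites), list(rho = -1.2))),
    "correlation")
  expect_error(sim_config(error_sd = 0), "error_sd")
  expect_error(sim_config(n_occasions = 1), "n_occasions")
})

test_that("isotope samples carry the transformed-uniform window mean", {
  cfg <- sim_config(seed = 2)
  expect_equal(nrow(sim_isotope_samples(cfg, 0)), 0)
  s <- sim_isotope_samples(cfg, 10000)
  boreal <- s[s$true_destination == "boreal", ]
  # closed form: mean feather value of 0.95 * U(-130, -70) - 17.57 = -112.57
  sd_f <- sqrt(0.95^2 * 60^2 / 12 + 5.5^2)
  expect_lt(abs(mean(boreal$d2h_f) - -112.57), 3 * sd_f / sqrt(nrow(boreal)))
  # true precipitation values stay inside the window
  expect_true(all(boreal$d2h_p_true >= -130 & boreal$d2h_p_true <= -70))
})

test_that("capture histories realise the transient/resident mixture", {
  # all transients: nothing after occasion 1
  h1 <- sim_histories(200, tau = 1, phi = 0.7, p = 0.9, seed = 1)
  expect_true(all(rowSums(h1[paste0("occ", 2:9)]) == 0))
  # binomial oracle: p = 1, tau = 0, phi = 0.5, two occasions
  h2 <- sim_histories(10000, tau = 0, phi = 0.5, p = 1, n_occasions = 2,
                      seed = 2)
  expect_lt(abs(mean(h2$occ2) - 0.5), 3 * sqrt(0.25 / 10000))
  # apparent first-interval persistence is (1 - tau) * phi
  h3 <- sim_histories(10000, tau = 0.5, phi = 0.7, p = 1, n_occasions = 2,
                      seed = 3)
  expect_lt(abs(mean(h3$occ2) - 0.35), 3 * sqrt(0.35 * 0.65 / 10000))
  expect_equal(nrow(sim_histories(0, 0.5, 0.5, 0.5)), 0)
})

test_that("metabolite residual correlation and degenerate cases behave", {
  # no covariate effects: marginal ln-scale correlation equals the residual one
  cfg <- sim_config(seed = 4, n_birds_per_group = 625,
                    metabolites = list(
                      intercepts = c(trig = 1.17, bohb = 0.96),
                      sd = c(trig = 0.5, bohb = 0.35), rho = -0.46,
                      beta_condition = 0, beta_ln_bleedtime = 0,
                      group_offsets = list()))
  b <- sim_birds(cfg)
  pl <- sim_metabolites(cfg, b)
  r <- cor(log(pl$triglyceride + 1), log(pl$bohb + 1))
  expect_lt(abs(r - -0.46), 0.05)
  expect_true(all(pl$triglyceride > 0 & pl$bohb > 0))

  # zero residual SD and zero effects: constant concentrations
  cfg0 <- sim_config(seed = 5, n_birds_per_group = 5,
                     metabolites = list(
                       intercepts = c(trig = 1.17, bohb = 0.96),
                       sd = c(trig = 0, bohb = 0), rho = 0,
                       beta_condition = 0, beta_ln_bleedtime = 0,
                       group_offsets = list()))
  pl0 <- sim_metabolites(cfg0, sim_birds(cfg0))
  expect_lt(diff(range(pl0$triglyceride)), 1e-4)
  expect_lt(diff(range(pl0$bohb)), 1e-4)
})

test_that("PC1-scale effects are injected along the leading eigenvector", {
  # regression of PC1 scores on condition recovers the configured slope
  cfg <- sim_config(seed = 6, n_birds_per_group = 500,
                    metabolites = modifyList(
                      eval(formals(sim_config)$metabolites),
                      list(group_offsets = list())))
  b <- sim_birds(cfg)
  pl <- sim_metabolites(cfg, b)
  ri <- refueling_index(transform_metabolites(pl))
  d <- data.frame(score = ri$scores,
                  condition = condition_index(b$body_mass, b$wing_chord),
                  ln_bleed = log(pl$bleedtime + 1))
  fit <- lm(score ~ condition + ln_bleed, d)
  expect_lt(abs(coef(fit)["condition"] - 0.11), 2.5 * summary(fit)$coefficients["condition", 2])
  expect_lt(abs(coef(fit)["ln_bleed"] - -0.21), 2.5 * summary(fit)$coefficients["ln_bleed", 2])
})

test_that("a study dataset round-trips through its files with truth recorded", {
  cfg <- sim_config(seed = 8, n_birds_per_group = 5)
  dir <- withr::local_tempdir()
  out <- sim_study_dataset(cfg, dir)
  expect_true(all(file.exists(unlist(out$paths))))
  birds2 <- read.csv(out$paths$birds, stringsAsFactors = FALSE)
  expect_equal(birds2, out$birds, tolerance = 1e-12)
  hist2 <- read.csv(out$paths$histories_csv, stringsAsFactors = FALSE)
  expect_equal(hist2$occ1, out$histories$occ1)
  inp <- read_inp(out$paths$histories_inp)
  expect_equal(as.matrix(inp[paste0("occ", 1:9)]),
               as.matrix(out$histories[paste0("occ", 1:9)]),
               ignore_attr = TRUE)
  truth <- yaml::read_yaml(out$paths$truth)
  expect_equal(truth$seed, 8)
  expect_equal(truth$destinations$boreal$tau, 0.516)
  expect_equal(truth$metabolites$beta_condition, 0.11)

  # empty configuration still writes schema-valid files
  cfg0 <- sim_config(seed = 9, n_birds_per_group = 0)
  dir0 <- withr::local_tempdir()
  out0 <- sim_study_dataset(cfg0, dir0)
  expect_equal(nrow(read.csv(out0$paths$birds)), 0)
  expect_equal(nrow(read.csv(out0$paths$plasma)), 0)
})
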