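# joint fixture: synthetic plasma + bird tables at a given size
make_study <- function(seed, n_per_group = 12, offsets = NULL) {
  mets <- eval(formals(sim_config)$metabolites)
  if (!is.null(offsets)) mets$group_offsets <- offsets
  cfg <- sim_config(seed = seed, n_birds_per_group = n_per_group,
                    metabolites = mets)
  b <- sim_birds(cfg)
  b$destination <- b$true_destination
  b$timing <- b$true_timing
  b$condition <- condition_index(b$body_mass, b$wing_chord)
  list(birds = b[c("bird_id", "destination", "timing", "condition",
                   "age", "sex")],
       plasma = sim_metabolites(cfg, b))
}

test_that("the two-tier analysis wires both selection tables together", {
  st <- make_study(101)
  res <- two_tier_refueling_analysis(st$plasma, st$birds)
  expect_s3_class(res, "refuel_analysis")
  expect_equal(nrow(res$tier1$table), 16)
  expect_equal(res$n_candidates, 144)
  # tier-1 winners are forced into every non-null tier-2 model
  nonnull <- Filter(function(f) length(f$terms) > 0, res$tier2$fits)
  expect_true(all(vapply(nonnull, function(f) {
    all(res$tier1_winners %in% f$terms)
  }, logical(1))))
  # weights sum to one in both tiers
  expect_equal(sum(res$tier1$table$weight), 1, tolerance = 1e-12)
  expect_equal(sum(res$tier2$table$weight), 1, tolerance = 1e-12)
  # dummy coding against the stated reference levels
  cn <- unlist(lapply(res$tier2$fits, function(f) names(f$coef)))
  expect_false(any(grepl("destinationsoutheast|sexF|ageSY|timingearly", cn)))
  # group-mean grid covers destination x timing
  expect_equal(nrow(res$group_means), 6)
  expect_true(all(is.finite(res$group_means$se)))
})

test_that("a strong bleed-time-only signal wins tier 1", {
  # no biological structure; only the methodological covariate acts
  st <- make_study(202, n_per_group = 25,
                   offsets = list(southeast = c(early = 0, middle = 0, late = 0),
                                  boreal = c(early = 0, middle = 0, late = 0)))
  res <- two_tier_refueling_analysis(st$plasma, st$birds)
  expect_true("ln_bleedtime" %in% res$tier1_winners)
})

test_that("generating group structure is recovered in the tier-2 averages", {
  st <- make_study(303, n_per_group = 40)
  res <- two_tier_refueling_analysis(st$plasma, st$birds)
  gm <- res$group_means
  pick <- function(d, t) gm$refuel[gm$destination == d & gm$timing == t]
  # generated pattern: southeast early/late high, southeast middle low
  expect_gt(pick("southeast", "early"), pick("southeast", "middle"))
  expect_gt(pick("southeast", "late"), pick("southeast", "middle"))
  # condition effect present with high relative importance
  av <- res$averaged
  cond <- av[av$coefficient == "condition", ]
  expect_lt(abs(cond$estimate - 0.11), 3 * cond$se)
  expect_gt(cond$w_plus, 0.5)
})

test_that("null generating data keeps the null model competitive", {
  # zero effects everywhere: selection over 144 candidates still leaves the
  # null close to the front; the best spurious model gains a few AICc units
  # at most (Freedman-type chance capitalisation, so the null is not in the
  # delta <= 4 set every time)
  deltas <- numeric(0)
  for (s in 1:12) {
    mets <- eval(formals(sim_config)$metabolites)
    mets$beta_condition <- 0
    mets$beta_ln_bleedtime <- 0
    mets$group_offsets <- list()
    cfg <- sim_config(seed = 500 + s, n_birds_per_group = 11,
                      metabolites = mets)
    b <- sim_birds(cfg)
    b$destination <- b$true_destination
    b$timing <- b$true_timing
    b$condition <- condition_index(b$body_mass, b$wing_chord)
    pl <- sim_metabolites(cfg, b)
    res <- two_tier_refueling_analysis(
      pl, b[c("bird_id", "destination", "timing", "condition", "age", "sex")])
    tab <- res$tier2$table
    deltas <- c(deltas, tab$delta[tab$model == "null"])
  }
  expect_gte(sum(deltas <= 4), 3)
  expect_lt(mean(deltas), 9)
})

test_that("degenerate joins are rejected", {
  st <- make_study(404, n_per_group = 5)
  empty_birds <- st$birds[0, ]
  expect_error(two_tier_refueling_analysis(st$plasma, empty_birds),
               "empty join")
})
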