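# stopover

Tools for analysing the spring stopover strategies of migratory songbirds
from banding-station data. The package is aimed at movement and stopover
ecologists working with the standard data streams of a coastal migration
station: feather stable-isotope samples, banding records, plasma
metabolite assays, and daily recapture/resight histories.

It implements four linked analyses:

1. **Breeding-destination assignment** (`assign_destinations()`): feather
   δ²H values are converted to precipitation equivalents through the
   calibration δ²H_f = 0.95 δ²H_p − 17.57, and each bird's probability of
   origin in two disjoint δ²H_p windows (southeast −10…−50‰, boreal forest
   −70…−130‰) is estimated by Monte-Carlo error propagation (1000 draws,
   SD 5.5‰). `reclassify_isoscape()` turns an isoscape grid into nested
   50/75/90% probability-of-origin categories.
2. **Condition and timing** (`condition_index()`,
   `assign_timing_classes()`): size-corrected migratory condition (body
   mass minus lean mass predicted from wing chord) and early/middle/late
   timing classes cut from each year × sex × destination group's
   capture-date range.
3. **Refueling index and two-tier AICc selection**
   (`refueling_index()`, `two_tier_refueling_analysis()`): the leading
   covariance principal component of ln(x+1) plasma triglyceride and
   β-hydroxy-butyrate scores each bird's fuel-deposition rate; a
   methodological tier (bleed time, time of day, date, year; 15 models +
   null) feeds a biological tier (destination, timing, condition, age,
   sex with hierarchical second-order interactions; 144 candidates),
   ranked by AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), with model-averaged
   coefficients, Burnham–Anderson unconditional SEs and relative
   importance w₊(j).
4. **Transient-aware Cormack–Jolly–Séber stopover model** (`fit_cjs()`,
   `stopover_model_selection()`): daily site persistence φ with two
   time-since-marking classes (φ₁ first interval, φ₂ after) and detection
   p on logit-linear predictors, fitted by maximum likelihood on collapsed
   nine-occasion encounter histories. Derived estimates: expected stopover
   duration −1/ln(φ₂) and transient probability τ = 1 − φ₁/φ₂, both with
   delta-method SEs.

A synthetic-study generator (`sim_config()`, `sim_study_dataset()`)
reproduces the statistical structure of all four data streams, so the
whole chain is testable without field data, and `run_pipeline()` runs
simulate → assign → prep → refuel → stopover end-to-end with a Markdown
report.

## Worked example

```r
library(stopover)

cfg   <- sim_config(seed = 42)               # default synthetic study
study <- sim_study_dataset(cfg, tempdir())   # birds/plasma/histories files

## destination assignment from feather isotopes
assign <- assign_destinations(study$birds[c("bird_id", "d2h_f")], seed = 42)
table(assign$destination)
#>     boreal  southeast unassigned
#>         77         65         18

## refueling index
ri <- refueling_index(transform_metabolites(study$plasma))
ri
#> Refueling index (covariance PCA of ln+1 metabolites)
#>   n = 160 birds
#>   loadings: triglyceride +0.923, BOHB -0.386
#>   PC1 variance explained: 77.0%

## transient-aware CJS on simulated histories
h   <- sim_histories(1000, tau = 0.533, phi = 0.75, p = 0.4,
                     n_occasions = 9, seed = 42)
fit <- fit_cjs(h)
fit
#> Transient-aware CJS model: phi1(1) phi2(1) p(1)
#>   n released = 1000, logLik = -1414.035, k = 3, AICc = 2834.09
#>                  estimate     se
#> phi1:(Intercept)  -0.8185 0.0919
#> phi2:(Intercept)   1.2526 0.0945
#> p:(Intercept)     -0.4063 0.0816

est <- predict(fit)
transient_probability(est["phi1", "estimate"], est["phi2", "estimate"])$percent
#> [1] 60.58  (generating value 53.3; ~1.6 SE away at this seed)
expected_stopover_duration(est["phi2", "estimate"])
#> [1] 3.98 days
```

The 18 unassigned birds fall in the −50…−70‰ gap between the destination
windows (or outside both); the loadings' signs mean high scores = fast
refueling. The CJS estimates are on the logit scale in the print; real
scale via `predict()`.

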