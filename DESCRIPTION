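Package: stopover
Title: Stopover Ecology of Migratory Songbirds: Isotope Assignment,
    Refueling Indices and Transient-Aware Capture-Recapture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing spring stopover strategies of migratory
    landbirds from banding-station data. Converts feather stable-hydrogen
    isotope values to precipitation equivalents and assigns breeding
    destinations with Monte-Carlo error propagation; computes size-corrected
    migratory condition and range-based migration-timing classes; builds a
    plasma-metabolite refueling index (covariance PCA of ln-transformed
    triglyceride and beta-hydroxy-butyrate) with two-tier AICc model
    selection, model averaging and relative-importance weights; and fits
    Cormack-Jolly-Seber models with time-since-marking (transient) structure
    to collapsed encounter histories, deriving expected stopover duration and
    transient probability with delta-method variances. Includes a synthetic
    data generator reproducing the statistical structure the analysis
    assumes, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
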