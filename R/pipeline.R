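# End-to-end pipeline: simulate (or read) -> assign destinations -> prep
# (condition + timing) -> refueling analysis -> stopover analysis, with a
# run log and a summary report.

#' Build a pipeline configuration
#'
#' Either `simulate` (a [sim_config()]) or explicit input `paths`
#' (`birds`, `plasma`, `histories`) must be given.
#'
#' @param out_dir Output directory.
#' @param simulate Optional [sim_config()]; when present the pipeline
#'   generates its own inputs.
#' @param paths Optional named list of input file paths.
#' @param seed Global seed (defaults to the simulate config's seed).
#' @param error_sd,n_draws Assignment-stage parameters.
#' @param delta_max Competing-set threshold for both AICc stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, paths = NULL,
                            seed = NULL, error_sd = 5.5, n_draws = 1000L,
                            delta_max = 4) {
  if (is.null(simulate) && is.null(paths)) {
    stop("either a simulate block or input paths are required", call. = FALSE)
  }
  if (!is.null(paths)) {
    missing <- setdiff(c("birds", "plasma", "histories"), names(paths))
    if (length(missing)) stop("missing input paths: ",
                              paste(missing, collapse = ", "), call. = FALSE)
    for (p in unlist(paths)) {
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    }
  }
  seed <- seed %||% (if (!is.null(simulate)) simulate$seed else 1L)
  structure(list(out_dir = out_dir, simulate = simulate, paths = paths,
                 seed = as.integer(seed), error_sd = error_sd,
                 n_draws = as.integer(n_draws), delta_max = delta_max),
            class = "pipeline_config")
}

#' Validate pipeline input files
#'
#' Schema checks (required columns, value ranges), cross-file id joins and
#' duplicate-band detection. Problems are collected, not thrown.
#'
#' @param paths Named list with `birds`, `plasma`, `histories` file paths.
#' @return List with `errors` and `warnings` (character vectors).
#' @export
validate_inputs <- function(paths) {
  errors <- character(0); warnings <- character(0)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) sprintf("%s: missing columns %s", what,
                              paste(miss, collapse = ", "))
    else character(0)
  }
  birds <- utils::read.csv(paths$birds, stringsAsFactors = FALSE)
  plasma <- utils::read.csv(paths$plasma, stringsAsFactors = FALSE)
  hist <- utils::read.csv(paths$histories, stringsAsFactors = FALSE)
  errors <- c(errors,
              need(birds, c("bird_id", "day_of_year", "year", "sex", "age",
                            "wing_chord", "body_mass", "d2h_f"), "birds"),
              need(plasma, c("bird_id", "triglyceride", "bohb", "bleedtime"),
                   "plasma"),
              need(hist, c("bird_id", "occ1"), "histories"))
  if (!length(errors)) {
    if (any(birds$wing_chord <= 0, na.rm = TRUE)) {
      errors <- c(errors, "birds: non-positive wing_chord")
    }
    if (any(birds$body_mass <= 0, na.rm = TRUE)) {
      errors <- c(errors, "birds: non-positive body_mass")
    }
    if (any(plasma$triglyceride <= 0 | plasma$bohb <= 0, na.rm = TRUE)) {
      errors <- c(errors, "plasma: non-positive metabolite concentration")
    }
    if (any(plasma$bleedtime < 0, na.rm = TRUE)) {
      errors <- c(errors, "plasma: negative bleedtime")
    }
    if (anyDuplicated(birds$bird_id)) {
      warnings <- c(warnings, "birds: duplicate band (bird_id) entries")
    }
    orphan <- setdiff(plasma$bird_id, birds$bird_id)
    if (length(orphan)) {
      warnings <- c(warnings, sprintf(
        "plasma: %d bird_id(s) absent from birds table", length(orphan)))
    }
    orphan_h <- setdiff(hist$bird_id, birds$bird_id)
    if (length(orphan_h)) {
      warnings <- c(warnings, sprintf(
        "histories: %d bird_id(s) absent from birds table", length(orphan_h)))
    }
  }
  list(errors = errors, warnings = warnings)
}

default_stopover_candidates <- function() {
  list(
    "null" = list(phi1 = ~1, phi2 = ~1),
    "destination" = list(phi1 = ~destination, phi2 = ~destination),
    "timing" = list(phi1 = ~timing, phi2 = ~timing),
    "sex" = list(phi1 = ~sex, phi2 = ~sex),
    "condition" = list(phi1 = ~1, phi2 = ~condition),
    "destination+condition" = list(phi1 = ~destination,
                                   phi2 = ~destination + condition))
}

#' Run the full stopover pipeline
#'
#' Executes simulate (or read) -> isotope assignment -> condition/timing
#' prep -> two-tier refueling analysis -> transient-aware CJS stopover
#' analysis, writing per-stage CSV outputs, a run log and a Markdown
#' summary report into `config$out_dir`. A stage failure aborts with the
#' failing stage named; outputs of completed stages are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run-log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat(sprintf("pipeline run %s\nseed: %d\nR: %s\n",
              format(Sys.time(), "%Y-%m-%d"), config$seed,
              as.character(getRversion())), file = log_path)
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    out <- tryCatch(expr, error = function(e) {
      logf("stage %s: FAILED (%s)", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    logf("stage %s: done", name)
    out
  }

  inputs <- stage("simulate", {
    if (!is.null(config$simulate)) {
      sim_study_dataset(config$simulate,
                        file.path(config$out_dir, "inputs"))$paths[
        c("birds", "plasma", "histories_csv")]
    } else config$paths
  })
  names(inputs) <- c("birds", "plasma", "histories")

  val <- validate_inputs(inputs)
  for (w in val$warnings) logf("validate: warning: %s", w)
  if (length(val$errors)) {
    stop("pipeline stage 'validate' failed: ",
         paste(val$errors, collapse = "; "), call. = FALSE)
  }

  birds <- utils::read.csv(inputs$birds, stringsAsFactors = FALSE)
  plasma <- utils::read.csv(inputs$plasma, stringsAsFactors = FALSE)
  hist <- utils::read.csv(inputs$histories, stringsAsFactors = FALSE)

  assign_res <- stage("assign", {
    out <- assign_destinations(birds[c("bird_id", "d2h_f")],
                               error_sd = config$error_sd,
                               n_draws = config$n_draws, seed = config$seed)
    utils::write.csv(out, file.path(config$out_dir, "assignments.csv"),
                     row.names = FALSE)
    out
  })

  birds <- stage("prep", {
    birds$destination <- assign_res$destination[match(birds$bird_id,
                                                      assign_res$bird_id)]
    birds$condition <- condition_index(birds$body_mass, birds$wing_chord)
    assigned <- birds[birds$destination != "unassigned", , drop = FALSE]
    assigned <- assign_timing_classes(assigned)
    birds$timing <- as.character(assigned$timing[match(birds$bird_id,
                                                       assigned$bird_id)])
    utils::write.csv(birds, file.path(config$out_dir, "birds-prepped.csv"),
                     row.names = FALSE)
    birds
  })

  refuel <- stage("refuel", {
    res <- two_tier_refueling_analysis(
      plasma, birds[c("bird_id", "destination", "timing", "condition",
                      "age", "sex")],
      delta_max = config$delta_max)
    utils::write.csv(res$tier1$table,
                     file.path(config$out_dir, "refuel-tier1.csv"),
                     row.names = FALSE)
    utils::write.csv(res$tier2$table,
                     file.path(config$out_dir, "refuel-tier2.csv"),
                     row.names = FALSE)
    utils::write.csv(res$averaged,
                     file.path(config$out_dir, "refuel-averaged.csv"),
                     row.names = FALSE)
    utils::write.csv(res$group_means,
                     file.path(config$out_dir, "refuel-group-means.csv"),
                     row.names = FALSE)
    res
  })

  stop_res <- stage("stopover", {
    # covariates come from the assigned + prepped bird table, not from any
    # columns the history file may carry
    hd <- hist[intersect(names(hist),
                         c("bird_id", grep("^occ", names(hist), value = TRUE),
                           "year", "year_group"))]
    idx <- match(hd$bird_id, birds$bird_id)
    hd$destination <- birds$destination[idx]
    hd$timing <- birds$timing[idx]
    hd$sex <- birds$sex[idx]
    hd$condition <- birds$condition[idx]
    if (is.null(hd$year)) hd$year <- birds$year[idx]
    if (is.null(hd$year_group)) {
      hd$year_group <- ifelse(hd$year == min(hd$year, na.rm = TRUE),
                              "first", "later")
    }
    hd <- hd[!is.na(hd$destination) & hd$destination != "unassigned" &
               !is.na(hd$timing), , drop = FALSE]
    p_formula <- if (length(unique(hd$year_group)) > 1L) ~year_group else ~1
    res <- stopover_model_selection(hd, default_stopover_candidates(),
                                    p_formula = p_formula,
                                    group_vars = c("destination", "timing", "sex"),
                                    delta_max = config$delta_max,
                                    seed = config$seed)
    utils::write.csv(res$aic$table,
                     file.path(config$out_dir, "stopover-aicc.csv"),
                     row.names = FALSE)
    utils::write.csv(res$estimates,
                     file.path(config$out_dir, "stopover-estimates.csv"),
                     row.names = FALSE)
    res
  })

  report <- stage("report", {
    path <- file.path(config$out_dir, "report.md")
    write_report(path, config, refuel, stop_res)
    path
  })

  invisible(list(inputs = inputs, assignments = assign_res, birds = birds,
                 refuel = refuel, stopover = stop_res, report = report,
                 validation = val))
}

write_report <- function(path, config, refuel, stop_res) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  lines <- c(
    "# Stopover pipeline summary",
    "",
    sprintf("Seed: %d", config$seed),
    "",
    "## Refueling index",
    sprintf("- PC1 variance explained: %s%%", fmt(100 * refuel$index$var_explained, 1)),
    sprintf("- Loadings: triglyceride %+0.2f, BOHB %+0.2f",
            refuel$index$loadings[1], refuel$index$loadings[2]),
    sprintf("- Tier-1 winner: %s", spec_label(refuel$tier1_winners)),
    sprintf("- Tier-2 candidates: %d", refuel$n_candidates),
    "",
    "## Predicted refueling index by destination x timing",
    "",
    "| destination | timing | index | SE |",
    "|---|---|---|---|",
    sprintf("| %s | %s | %s | %s |", refuel$group_means$destination,
            refuel$group_means$timing, fmt(refuel$group_means$refuel),
            fmt(refuel$group_means$se)),
    "",
    "## Stopover estimates (model-averaged)",
    "",
    "| group | n | duration (d) | SE | transient (%) | SE |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %d | %s | %s | %s | %s |",
            stop_res$estimates$group, stop_res$estimates$n,
            fmt(stop_res$estimates$duration, 2),
            fmt(stop_res$estimates$duration_se, 2),
            fmt(stop_res$estimates$transient_pct, 1),
            fmt(stop_res$estimates$transient_pct_se, 1)))
  writeLines(lines, path)
  invisible(path)
}
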