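# End-to-end orchestration: synthetic or CSV input -> accelerometry ->
# compositions -> regression -> isotemporal tables, plus report rendering.

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"csv"` (read epoch,
#'   participant and outcome CSVs from `input_dir`).
#' @param input_dir Directory holding `epochs.csv`, `participants.csv`,
#'   `outcomes.csv` when `mode = "csv"`.
#' @param output_dir Directory the run artifacts are written to (`NULL` =
#'   return artifacts only).
#' @param windows Analysis windows, a subset of
#'   `c("week", "weekend", "four_day")`; must be non-empty.
#' @param delta Reallocated minutes for the isotemporal tables (default 5).
#' @param closure_total Closure total in minutes (default 600).
#' @param wrist Cut-point wrist placement used when the epoch table lacks a
#'   `wrist` column.
#' @param min_days,min_weekend_days,min_wear_hours Inclusion thresholds
#'   (defaults 3, 1, 6).
#' @param seed RNG seed (synthetic mode).
#' @param generator A [generator_config()] for synthetic mode (`NULL` =
#'   defaults with this `seed`).
#' @param realloc_method `"clamp"` (default; donor floored at epsilon so
#'   every table cell is estimable) or `"exact"` (infeasible cells NA).
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "csv"), input_dir = NULL,
                       output_dir = NULL,
                       windows = c("week", "weekend", "four_day"),
                       delta = 5, closure_total = 600, wrist = "dominant",
                       min_days = 3, min_weekend_days = 1, min_wear_hours = 6,
                       seed = 1L, generator = NULL,
                       realloc_method = c("clamp", "exact")) {
  mode <- match.arg(mode)
  realloc_method <- match.arg(realloc_method)
  if (length(windows) == 0L ||
      !all(windows %in% c("week", "weekend", "four_day")))
    stop("windows must be a non-empty subset of week/weekend/four_day")
  if (delta <= 0) stop("delta must be positive")
  if (closure_total <= 0) stop("closure_total must be positive")
  if (mode == "csv" && (is.null(input_dir) || !dir.exists(input_dir)))
    stop("csv mode needs an existing input_dir")
  if (is.null(generator) && mode == "synthetic")
    generator <- generator_config(seed = seed)
  structure(list(mode = mode, input_dir = input_dir, output_dir = output_dir,
                 windows = windows, delta = delta,
                 closure_total = closure_total, wrist = wrist,
                 min_days = min_days, min_weekend_days = min_weekend_days,
                 min_wear_hours = min_wear_hours, seed = as.integer(seed),
                 generator = generator, realloc_method = realloc_method),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Compositional analysis of window minutes
#'
#' Shared analysis stage: closes each participant's window minutes (after
#' zero replacement), computes the descriptive geometric-mean composition
#' and the variation matrix, fits the ilr regressions for the three
#' outcomes, runs the composition Wald tests and diagnostics, the naive
#' single-behaviour regressions, and the isotemporal table at the sample
#' baseline.
#'
#' @param window_minutes Data frame `id`, `sb`, `lpa`, `mvpa` (minutes).
#' @param outcomes Data frame `id`, `total_mc`, `locomotor`,
#'   `object_control`.
#' @param covariates Matrix from [encode_covariates()] (rownames = ids).
#' @param closure_total Closure total (default 600).
#' @param delta Reallocation minutes (default 5).
#' @param realloc_method Passed to [isotemporal_table()].
#' @param window Label carried into the outputs.
#' @return List of analysis artifacts for the window.
#' @export
analyse_compositions <- function(window_minutes, outcomes, covariates,
                                 closure_total = 600, delta = 5,
                                 realloc_method = "clamp", window = "week") {
  ids <- intersect(window_minutes$id, outcomes$id)
  ids <- intersect(ids, rownames(covariates))
  if (length(ids) < 10L)
    stop("analysis window '", window, "' has too few participants (",
         length(ids), ")")
  wm <- window_minutes[match(ids, window_minutes$id), , drop = FALSE]
  ycols <- c("total_mc", "locomotor", "object_control")
  ys <- outcomes[match(ids, outcomes$id), ycols, drop = FALSE]
  cv <- covariates[ids, , drop = FALSE]

  raw <- as.matrix(wm[, behaviour_parts()])
  comp <- close_composition(zero_replace(raw), total = closure_total)
  z <- ilr_transform(comp)
  centre <- geometric_mean_composition(comp, total = closure_total)
  vmat <- variation_matrix(comp)

  fits <- lapply(stats::setNames(ycols, ycols), function(o)
    fit_ilr_regression(ys[[o]], z, cv, outcome = o))
  wald <- lapply(fits, composition_wald_test)
  diagnostics <- lapply(fits, run_diagnostics)
  naive <- list()
  for (o in ycols) for (p in behaviour_parts()) {
    naive[[paste(o, p, sep = ".")]] <-
      c(outcome = o, behaviour = p,
        fit_single_behaviour_regression(ys[[o]], raw[, p], cv))
  }
  iso <- isotemporal_table(fits, centre, delta = delta, method = realloc_method)
  iso$window <- window

  list(window = window, n = length(ids),
       descriptives = list(
         minutes = centre,
         proportions = close_composition(centre, total = 1)),
       variation = vmat, fits = fits, wald = wald,
       diagnostics = diagnostics, naive = naive, isotemporal = iso)
}

#' Run the full pipeline
#'
#' Sequences the stages: obtain epoch-level data (simulated or CSV),
#' summarize days and apply inclusion rules, derive window minutes, and run
#' the compositional analysis per window. When `output_dir` is set the
#' descriptives, variation matrices, regression summaries, isotemporal
#' tables, exclusion log and a manifest are written as CSV/JSON, plus the
#' rendered markdown report.
#'
#' @param config A [run_config()].
#' @return List of run artifacts (per-window analyses, day profiles,
#'   exclusions, guideline classification, manifest).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (config$mode == "synthetic") {
    cohort <- stage("simulate", simulate_cohort(config$generator, render_epochs = TRUE))
    epochs <- cohort$epochs
    participants <- cohort$participants
    outcomes <- cohort$outcomes
  } else {
    epochs <- stage("read", read_epochs_csv(file.path(config$input_dir, "epochs.csv")))
    participants <- stage("read", read_participants_csv(
      file.path(config$input_dir, "participants.csv")))
    outcomes <- stage("read", utils::read.csv(
      file.path(config$input_dir, "outcomes.csv"), stringsAsFactors = FALSE))
  }
  profiles <- stage("process", process_epochs(epochs, wrist = config$wrist))
  flt <- stage("filter", filter_valid_participants(
    profiles, min_days = config$min_days,
    min_weekend_days = config$min_weekend_days,
    min_wear_hours = config$min_wear_hours))
  covariates <- stage("covariates", encode_covariates(participants))
  guideline <- vapply(
    split(flt$valid_profiles, flt$valid_profiles$id),
    classify_guideline, character(1))

  analyses <- list()
  for (w in config$windows) {
    wm <- stage(paste0("window:", w),
                derive_window_minutes(flt$valid_profiles, window = w))
    analyses[[w]] <- stage(paste0("analyse:", w), analyse_compositions(
      wm, outcomes, covariates, closure_total = config$closure_total,
      delta = config$delta, realloc_method = config$realloc_method,
      window = w))
  }
  manifest <- list(
    mode = config$mode, seed = config$seed, windows = config$windows,
    delta = config$delta, closure_total = config$closure_total,
    n_input_participants = nrow(participants),
    n_retained = length(flt$retained),
    n_excluded = nrow(flt$exclusions),
    package_version = as.character(utils::packageVersion("codamove"))
  )
  artifacts <- list(analyses = analyses, profiles = profiles,
                    exclusions = flt$exclusions, retained = flt$retained,
                    guideline = guideline, manifest = manifest,
                    participants = participants, outcomes = outcomes)
  if (!is.null(config$output_dir)) write_artifacts(artifacts, config$output_dir)
  artifacts
}

write_artifacts <- function(artifacts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  desc <- do.call(rbind, lapply(artifacts$analyses, function(a) data.frame(
    window = a$window, part = behaviour_parts(),
    minutes = as.numeric(a$descriptives$minutes),
    proportion = as.numeric(a$descriptives$proportions))))
  utils::write.csv(desc, file.path(dir, "descriptives.csv"), row.names = FALSE)
  for (a in artifacts$analyses) {
    utils::write.csv(as.data.frame(a$variation),
                     file.path(dir, paste0("variation_", a$window, ".csv")))
  }
  iso <- do.call(rbind, lapply(artifacts$analyses, `[[`, "isotemporal"))
  utils::write.csv(iso, file.path(dir, "isotemporal.csv"), row.names = FALSE)
  naive <- do.call(rbind, lapply(artifacts$analyses, function(a)
    do.call(rbind, lapply(a$naive, function(x) data.frame(
      window = a$window, outcome = x$outcome, behaviour = x$behaviour,
      B = x$B, ci_low = x$ci[1], ci_high = x$ci[2], p = x$p_value, r2 = x$r2)))))
  utils::write.csv(naive, file.path(dir, "single_behaviour.csv"), row.names = FALSE)
  fits_json <- lapply(artifacts$analyses, function(a) list(
    window = a$window, n = a$n,
    fits = lapply(a$fits, function(f) list(
      outcome = f$outcome, coefficients = as.list(f$coefficients),
      r2 = f$r2, r2_composition = f$r2_composition)),
    wald = a$wald,
    sex_coding = "female=0, male=1",
    multiple_testing = "none (per-cell CIs)"))
  jsonlite::write_json(fits_json, file.path(dir, "model_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  if (nrow(artifacts$exclusions)) {
    writeLines(vapply(seq_len(nrow(artifacts$exclusions)), function(i)
      jsonlite::toJSON(as.list(artifacts$exclusions[i, ]), auto_unbox = TRUE),
      character(1)), file.path(dir, "exclusions.jsonl"))
  } else file.create(file.path(dir, "exclusions.jsonl"))
  jsonlite::write_json(artifacts$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  writeLines(render_tables(artifacts), file.path(dir, "report.md"))
  invisible(dir)
}

#' Render the human-readable report
#'
#' One markdown report mirroring the standard table layouts: sample
#' descriptives (minutes per day and closed proportions to 2 dp), the
#' behaviour variation matrix per window (symmetric, dashes on the
#' diagonal), the naive single-behaviour regressions, the compositional fit
#' summaries with Wald tests, and the six-pair isotemporal substitution
#' table per outcome and window.
#'
#' @param artifacts Result of [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
render_tables <- function(artifacts) {
  req <- c("analyses", "manifest")
  miss <- setdiff(req, names(artifacts))
  if (length(miss)) stop("missing artifact(s): ", paste(miss, collapse = ", "))
  lines <- c("# Movement composition analysis report", "")
  lab <- c(sb = "SB", lpa = "LPA", mvpa = "MVPA")
  wins <- names(artifacts$analyses)

  lines <- c(lines, "## Sample descriptive statistics", "",
             paste0("| | ", paste(wins, collapse = " | "), " |"),
             paste0("|---|", paste(rep("---|", length(wins)), collapse = "")))
  for (p in behaviour_parts()) {
    mins <- vapply(artifacts$analyses, function(a)
      sprintf("%.2f", a$descriptives$minutes[[p]]), character(1))
    props <- vapply(artifacts$analyses, function(a)
      sprintf("%.2f", a$descriptives$proportions[[p]]), character(1))
    lines <- c(lines,
               paste0("| ", lab[[p]], " (min/day) | ", paste(mins, collapse = " | "), " |"),
               paste0("| ", lab[[p]], " (comp) | ", paste(props, collapse = " | "), " |"))
  }
  lines <- c(lines, "", "## Behaviour variation matrix", "")
  for (a in artifacts$analyses) {
    lines <- c(lines, paste0("### ", a$window), "",
               paste0("| | ", paste(lab, collapse = " | "), " |"),
               "|---|---|---|---|")
    for (i in behaviour_parts()) {
      cells <- vapply(behaviour_parts(), function(j)
        if (i == j) "-" else sprintf("%.2f", a$variation[i, j]), character(1))
      lines <- c(lines, paste0("| ", lab[[i]], " | ", paste(cells, collapse = " | "), " |"))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "## Compositional model fits", "")
  for (a in artifacts$analyses) for (o in names(a$fits)) {
    f <- a$fits[[o]]
    w <- a$wald[[o]]
    lines <- c(lines, sprintf(
      "- %s / %s: r2 = %.3f, compositional r2 = %.3f, Wald chi2(2) = %.2f, p = %.4g",
      a$window, o, f$r2, f$r2_composition, w$statistic, w$p_value))
  }
  lines <- c(lines, "", "## Isotemporal substitution (5-min reallocations)", "")
  for (a in artifacts$analyses) {
    iso <- a$isotemporal
    lines <- c(lines, paste0("### ", a$window), "",
               "| outcome | add | remove | estimate | 95% CI | sig |",
               "|---|---|---|---|---|---|")
    for (r in seq_len(nrow(iso))) {
      if (is.na(iso$estimate[r])) {
        lines <- c(lines, sprintf("| %s | %s | %s | NA | %s | |",
                                  iso$outcome[r], lab[[iso$add[r]]],
                                  lab[[iso$remove[r]]], iso$note[r]))
      } else {
        lines <- c(lines, sprintf(
          "| %s | %s | %s | %.2f | (%.2f, %.2f) | %s |",
          iso$outcome[r], lab[[iso$add[r]]], lab[[iso$remove[r]]],
          iso$estimate[r], iso$ci_low[r], iso$ci_high[r],
          if (isTRUE(iso$significant[r])) "*" else ""))
      }
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, sprintf("Retained participants: %d (excluded: %d).",
                            artifacts$manifest$n_retained,
                            artifacts$manifest$n_excluded))
  lines
}
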