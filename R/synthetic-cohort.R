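# Seeded synthetic cohort: participants, day-level logistic-normal
# compositions, epoch-level accelerometer rendering, and FMS outcomes with
# known generative truth.

# Symmetric PSD square root (exact for the zero matrix, so a degenerate
# covariance reproduces the mean composition bit-for-bit).
psd_sqrt <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = length(e$values)) %*%
    t(e$vectors)
}

#' Synthetic cohort generator configuration
#'
#' Bundles and validates every knob of the synthetic cohort: sample size,
#' seed, day-type mean compositions and ilr covariances (defaulting to the
#' published calibration summaries in [movement_calibration()]), true
#' regression coefficients per outcome, outcome noise, epoch length, the
#' day schedule, and non-wear insertion.
#'
#' Compositions are drawn logistic-normally: a bivariate Gaussian on the ilr
#' scale centred at the ilr of the day-type mean composition, back-transformed
#' and closed to `closure_total` minutes. True outcomes follow
#' `y = b0 + b1 z1 + b2 z2 + b_age age + b_bmi bmi + b_sex sex + e`,
#' `e ~ N(0, noise_sd^2)`.
#'
#' @param n_participants Number of children (default 185).
#' @param seed Integer RNG seed.
#' @param weekday_mean_comp,weekend_mean_comp Length-3 positive proportions
#'   summing to 1 (SB, LPA, MVPA). Defaults: the week and weekend calibration
#'   compositions closed to 1.
#' @param ilr_covariance_weekday,ilr_covariance_weekend 2 x 2 symmetric
#'   positive-definite ilr covariances. Defaults derived from the week and
#'   weekend calibration variation matrices via
#'   [ilr_covariance_from_variation()].
#' @param true_beta Named list of length-6 coefficient vectors
#'   `(intercept, z1, z2, age, bmi, sex)` for outcomes `total_mc`,
#'   `locomotor`, `object_control`. Defaults calibrated so the weekday
#'   compositional semi-partial r-squared is about 0.07 / 0.08 / 0.09.
#' @param noise_sd Named numeric vector of outcome noise SDs (same names).
#' @param epoch_seconds Epoch length in seconds; must divide 60 (default 10).
#' @param days Character vector scheduling day types (default two weekdays
#'   and two weekend days).
#' @param nonwear_block_minutes Length of the contiguous non-wear block
#'   inserted inside the worn part of each rendered day (0 = none).
#' @param closure_total Minutes each day-level composition is closed to
#'   (default 600, a 10-h bounded day).
#' @param day_correlation Within-participant correlation of day-level ilr
#'   draws, in [0, 1) (default 0; the source data give no estimate).
#' @param sex_ratio Proportion of boys (default 99/185).
#' @param quota_sampling Logical; if `TRUE` the boy/girl split is exact
#'   (`round(n * sex_ratio)`), otherwise binomial.
#' @param bout_epochs Mean activity-bout length in epochs used when rendering
#'   epoch series (geometric bout lengths; default 6, i.e. 1 min).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 185,
                             seed = 1L,
                             weekday_mean_comp = NULL,
                             weekend_mean_comp = NULL,
                             ilr_covariance_weekday = NULL,
                             ilr_covariance_weekend = NULL,
                             true_beta = default_true_beta(),
                             noise_sd = default_noise_sd(),
                             epoch_seconds = 10L,
                             days = c("weekday", "weekday", "weekend", "weekend"),
                             nonwear_block_minutes = 0,
                             closure_total = 600,
                             day_correlation = 0,
                             sex_ratio = 99 / 185,
                             quota_sampling = FALSE,
                             bout_epochs = 6) {
  calib <- movement_calibration()
  if (is.null(weekday_mean_comp))
    weekday_mean_comp <- close_composition(calib$minutes$week, total = 1)
  if (is.null(weekend_mean_comp))
    weekend_mean_comp <- close_composition(calib$minutes$weekend, total = 1)
  if (is.null(ilr_covariance_weekday))
    ilr_covariance_weekday <- ilr_covariance_from_variation(calib$variation$week)
  if (is.null(ilr_covariance_weekend))
    ilr_covariance_weekend <- ilr_covariance_from_variation(calib$variation$weekend)

  stopifnot(length(n_participants) == 1L, is.finite(n_participants))
  if (n_participants < 1) stop("n_participants must be at least 1")
  check_mean <- function(p, what) {
    if (length(p) != 3L || any(p <= 0) || abs(sum(p) - 1) > 1e-8)
      stop(what, " must be 3 strictly positive proportions summing to 1")
  }
  check_mean(weekday_mean_comp, "weekday_mean_comp")
  check_mean(weekend_mean_comp, "weekend_mean_comp")
  check_cov <- function(s, what) {
    s <- as.matrix(s)
    if (!all(dim(s) == c(2L, 2L)) || max(abs(s - t(s))) > 1e-10 ||
        any(eigen(s, symmetric = TRUE, only.values = TRUE)$values < 0))
      stop(what, " must be a symmetric positive semi-definite 2 x 2 matrix")
    s
  }
  ilr_covariance_weekday <- check_cov(ilr_covariance_weekday, "ilr_covariance_weekday")
  ilr_covariance_weekend <- check_cov(ilr_covariance_weekend, "ilr_covariance_weekend")
  outs <- c("total_mc", "locomotor", "object_control")
  if (!all(outs %in% names(true_beta)) ||
      !all(vapply(true_beta, length, 1L) == 6L))
    stop("true_beta must name length-6 vectors for ", paste(outs, collapse = ", "))
  if (!all(outs %in% names(noise_sd)) || any(noise_sd <= 0))
    stop("noise_sd must be positive and named for each outcome")
  if (60 %% epoch_seconds != 0) stop("epoch_seconds must divide 60")
  if (!all(days %in% c("weekday", "weekend"))) stop("days must be 'weekday'/'weekend'")
  if (day_correlation < 0 || day_correlation >= 1)
    stop("day_correlation must be in [0, 1)")
  if (nonwear_block_minutes < 0) stop("nonwear_block_minutes must be >= 0")
  if (closure_total <= 0 || closure_total > 1440) stop("closure_total must be in (0, 1440]")

  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    weekday_mean_comp = stats::setNames(as.numeric(weekday_mean_comp), behaviour_parts()),
    weekend_mean_comp = stats::setNames(as.numeric(weekend_mean_comp), behaviour_parts()),
    ilr_covariance_weekday = ilr_covariance_weekday,
    ilr_covariance_weekend = ilr_covariance_weekend,
    true_beta = true_beta, noise_sd = noise_sd,
    epoch_seconds = as.integer(epoch_seconds), days = days,
    nonwear_block_minutes = nonwear_block_minutes,
    closure_total = closure_total, day_correlation = day_correlation,
    sex_ratio = sex_ratio, quota_sampling = isTRUE(quota_sampling),
    bout_epochs = bout_epochs
  ), class = "generator_config")
}

coef_names <- function() c("intercept", "z1", "z2", "age", "bmi", "sex")

#' @rdname generator_config
#' @export
default_true_beta <- function() {
  nm <- coef_names()
  list(
    total_mc       = stats::setNames(c(45, -1.5, 2.5, 2.0, -0.5, 2.0), nm),
    locomotor      = stats::setNames(c(25, -1.1, 1.9, 1.5, -0.3, 0.5), nm),
    object_control = stats::setNames(c(18, -0.9, 1.6, 1.2, -0.2, 1.5), nm)
  )
}

#' @rdname generator_config
#' @export
default_noise_sd <- function() {
  c(total_mc = 5.2, locomotor = 3.7, object_control = 2.83)
}

#' Generate synthetic participants
#'
#' Draws ages uniformly on [3, 4] years, sex by the configured boy ratio
#' (binomial, or an exact quota split), heights uniformly on a plausible
#' preschool range and BMI normally around 16.3 kg/m^2; mass follows from
#' BMI and height.
#'
#' @param config A [generator_config()].
#' @return Data frame with columns `id`, `age`, `sex` ("male"/"female"),
#'   `height`, `mass`, `bmi`.
#' @export
generate_participants <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_participants
  withr_seed(config$seed, {
    if (config$quota_sampling) {
      n_boys <- round(n * config$sex_ratio)
      sex <- sample(rep(c("male", "female"), c(n_boys, n - n_boys)))
    } else {
      sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
    }
    age <- stats::runif(n, 3, 4)
    height <- stats::runif(n, 0.93, 1.10)
    bmi <- stats::rnorm(n, 16.3, 1.4)
    bmi <- pmin(pmax(bmi, 12), 22)
    data.frame(
      id = sprintf("P%04d", seq_len(n)),
      age = age, sex = sex, height = height,
      mass = bmi * height^2, bmi = bmi,
      stringsAsFactors = FALSE
    )
  })
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Generate day-level true behaviour compositions
#'
#' For each participant and scheduled day, draws ilr coordinates from a
#' bivariate Gaussian centred at the ilr of the day-type mean composition
#' with the day-type ilr covariance, optionally sharing a participant-level
#' component (`day_correlation`), then back-transforms and closes each day to
#' `closure_total` minutes.
#'
#' @param config A [generator_config()].
#' @param participants Data frame from [generate_participants()].
#' @return Data frame with columns `id`, `day_index`, `day_type`, `sb`,
#'   `lpa`, `mvpa` (minutes; each row sums to `closure_total`).
#' @export
generate_day_compositions <- function(config, participants) {
  stopifnot(inherits(config, "generator_config"))
  n <- nrow(participants)
  days <- config$days
  basis <- ilr_basis()
  mu <- list(
    weekday = ilr_transform(config$weekday_mean_comp, basis),
    weekend = ilr_transform(config$weekend_mean_comp, basis)
  )
  L <- list(
    weekday = psd_sqrt(config$ilr_covariance_weekday),
    weekend = psd_sqrt(config$ilr_covariance_weekend)
  )
  rho <- config$day_correlation
  nd <- length(days)
  withr_seed(config$seed + 1L, {
    u <- matrix(stats::rnorm(n * 2), nrow = n)          # shared participant effect
    e <- matrix(stats::rnorm(n * nd * 2), nrow = n * nd)
    mix <- sqrt(rho) * u[rep(seq_len(n), each = nd), , drop = FALSE] +
      sqrt(1 - rho) * e
    day_type <- rep(days, times = n)
    z <- matrix(NA_real_, n * nd, 2)
    for (dt in unique(days)) {
      sel <- day_type == dt
      z[sel, ] <- sweep(mix[sel, , drop = FALSE] %*% L[[dt]], 2L, mu[[dt]], "+")
    }
    comp <- ilr_inverse(z, total = config$closure_total, basis = basis)
    data.frame(
      id = rep(participants$id, each = nd),
      day_index = rep(seq_len(nd), times = n),
      day_type = day_type,
      sb = comp[, "sb"], lpa = comp[, "lpa"], mvpa = comp[, "mvpa"],
      stringsAsFactors = FALSE
    )
  })
}

#' Render a day of epoch-level accelerometer magnitudes
#'
#' Expands one day-level composition into a 24-h series of epoch magnitudes:
#' a leading non-wear (zero) block covering the unworn remainder of the day,
#' the worn time arranged in geometric-length activity bouts whose per-class
#' epoch counts reproduce the composition minutes exactly up to epoch
#' granularity, and optionally one inserted contiguous non-wear block of
#' `nonwear_block_minutes` placed midway through the worn period. Magnitudes
#' are drawn uniformly strictly inside each intensity band (MVPA inside
#' [lpa_upper, 2 lpa_upper]) so cut-point ties cannot occur.
#'
#' @param composition Length-3 minutes (SB, LPA, MVPA); total + inserted
#'   non-wear must fit in 1440 min.
#' @param config A [generator_config()].
#' @param seed Integer seed for this day's draws.
#' @param date Calendar `Date` of the rendered day.
#' @param wrist Wrist placement whose cut points bound the bands.
#' @param id Participant id stamped on the rows.
#' @return Data frame of class `epoch_series` with attribute
#'   `epoch_seconds`; columns `id`, `time` (POSIXct, UTC), `svm`, `wrist`.
#' @export
render_epoch_series <- function(composition, config, seed,
                                date = as.Date("2016-06-02"),
                                wrist = "dominant", id = "day") {
  comp <- as_comp_matrix(composition)[1L, ]
  if (any(comp < 0)) stop("composition minutes must be non-negative")
  es <- config$epoch_seconds
  epm <- 60L / es                                     # epochs per minute
  n_day <- as.integer(86400 / es)
  wear_ep <- largest_remainder(comp * epm)
  nw_ep <- as.integer(round(config$nonwear_block_minutes * epm))
  if (sum(wear_ep) + nw_ep > n_day)
    stop("composition plus inserted non-wear exceeds the 24-h day")
  cp <- cut_points(wrist)
  bands <- list(
    sb   = c(cp$sb_upper * 0.05, cp$sb_upper * 0.95),
    lpa  = c(cp$sb_upper + 0.05 * (cp$lpa_upper - cp$sb_upper),
             cp$lpa_upper - 0.05 * (cp$lpa_upper - cp$sb_upper)),
    mvpa = c(cp$lpa_upper * 1.05, cp$lpa_upper * 2)
  )
  withr_seed(seed, {
    labels <- bout_sequence(wear_ep, config$bout_epochs)
    svm_wear <- numeric(length(labels))
    for (cls in behaviour_parts()) {
      idx <- labels == cls
      if (any(idx))
        svm_wear[idx] <- stats::runif(sum(idx), bands[[cls]][1], bands[[cls]][2])
    }
    # insert the non-wear block midway through the worn period
    if (nw_ep > 0L) {
      at <- floor(length(svm_wear) / 2)
      svm_wear <- append(svm_wear, rep(0, nw_ep), after = at)
    }
    lead <- n_day - length(svm_wear)
    svm <- c(rep(0, lead), svm_wear)
    t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
    out <- data.frame(
      id = id,
      time = t0 + seq(0, by = es, length.out = n_day),
      svm = svm, wrist = wrist, stringsAsFactors = FALSE
    )
    attr(out, "epoch_seconds") <- es
    class(out) <- c("epoch_series", "data.frame")
    out
  })
}

# Integer apportionment preserving the total (largest-remainder rule).
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- as.integer(round(sum(x)) - sum(fl))
  if (rem > 0L) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(fl), names(x))
}

# Arrange per-class epoch counts into alternating geometric-length bouts.
bout_sequence <- function(counts, mean_bout) {
  remaining <- counts
  out <- character(sum(counts))
  k <- 0L
  while (sum(remaining) > 0L) {
    cls <- sample(names(remaining), 1L, prob = remaining / sum(remaining))
    len <- min(1L + stats::rgeom(1L, 1 / mean_bout), remaining[[cls]])
    out[k + seq_len(len)] <- cls
    k <- k + len
    remaining[[cls]] <- remaining[[cls]] - len
  }
  out
}

#' Generate FMS outcomes from true compositions
#'
#' Applies the configured linear model on ilr coordinates plus covariates,
#' adding Gaussian noise, and returns both the observed outcomes and the
#' generative truth (linear predictors and realized noise).
#'
#' @param compositions One composition per participant: data frame or matrix
#'   with columns `sb`, `lpa`, `mvpa` (rows aligned with `participants`).
#' @param participants Data frame from [generate_participants()].
#' @param config A [generator_config()].
#' @return List with `outcomes` (data frame `id`, `total_mc`, `locomotor`,
#'   `object_control`) and `truth` (per-outcome linear predictors, noise,
#'   the ilr coordinates used, and a config echo).
#' @export
generate_fms_outcomes <- function(compositions, participants, config) {
  stopifnot(inherits(config, "generator_config"))
  comp <- as_comp_matrix(compositions)
  if (nrow(comp) != nrow(participants))
    stop("need exactly one composition per participant (got ",
         nrow(comp), " for ", nrow(participants), " participants)")
  z <- ilr_transform(comp)
  X <- cbind(1, z,
             age = participants$age, bmi = participants$bmi,
             sex = as.numeric(participants$sex == "male"))
  colnames(X) <- coef_names()
  rownames(X) <- NULL
  withr_seed(config$seed + 2L, {
    outs <- names(config$true_beta)
    lp <- noise <- stats::setNames(vector("list", length(outs)), outs)
    res <- data.frame(id = participants$id, stringsAsFactors = FALSE)
    for (o in outs) {
      lp[[o]] <- drop(X %*% config$true_beta[[o]])
      noise[[o]] <- stats::rnorm(nrow(X), 0, config$noise_sd[[o]])
      res[[o]] <- lp[[o]] + noise[[o]]
    }
    list(outcomes = res,
         truth = list(linear_predictor = lp, noise = noise, ilr = z,
                      config = config))
  })
}

#' Simulate a full synthetic cohort
#'
#' Runs the whole generator: participants, day-level true compositions,
#' per-participant mean ilr (across all scheduled days) from which the FMS
#' outcomes are generated, and optionally rendered epoch-level accelerometer
#' series for every participant-day.
#'
#' @param config A [generator_config()].
#' @param render_epochs Logical; also render epoch series (slower).
#' @param start_date First calendar date; scheduled day types are mapped to
#'   consecutive dates whose weekday/weekend status matches the schedule.
#' @return List with `participants`, `day_compositions`, `outcomes`,
#'   `truth`, and (optionally) `epochs` (one `epoch_series` per
#'   participant-day, row-bound).
#' @export
simulate_cohort <- function(config, render_epochs = FALSE,
                            start_date = as.Date("2016-06-02")) {
  participants <- generate_participants(config)
  day_comps <- generate_day_compositions(config, participants)
  # outcome-generating composition: per-participant mean on the ilr scale
  z <- ilr_transform(day_comps[, behaviour_parts()])
  zbar <- rowsum(z, day_comps$id)
  zbar <- zbar / as.vector(table(day_comps$id)[rownames(zbar)])
  zbar <- zbar[participants$id, , drop = FALSE]
  gen_comp <- ilr_inverse(zbar, total = config$closure_total)
  fms <- generate_fms_outcomes(gen_comp, participants, config)
  out <- list(participants = participants, day_compositions = day_comps,
              outcomes = fms$outcomes, truth = fms$truth, config = config)
  if (render_epochs) {
    dates <- schedule_dates(config$days, start_date)
    ep <- vector("list", nrow(day_comps))
    for (r in seq_len(nrow(day_comps))) {
      comp <- as.numeric(day_comps[r, behaviour_parts()])
      ep[[r]] <- render_epoch_series(
        comp, config,
        seed = config$seed + 1000L + r,
        date = dates[day_comps$day_index[r]],
        id = day_comps$id[r]
      )
    }
    epochs <- do.call(rbind, ep)
    attr(epochs, "epoch_seconds") <- config$epoch_seconds
    class(epochs) <- c("epoch_series", "data.frame")
    out$epochs <- epochs
  }
  out
}

# Map a weekday/weekend schedule onto consecutive calendar dates starting at
# or after start_date such that each date's Sat/Sun status matches.
schedule_dates <- function(days, start_date) {
  dates <- as.Date(character(0))
  d <- start_date
  for (dt in days) {
    repeat {
      is_wkd <- format(d, "%u") %in% c("6", "7")
      if ((dt == "weekend") == is_wkd) break
      d <- d + 1
    }
    dates <- c(dates, d)
    d <- d + 1
  }
  dates
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the epoch CSV (`participant_id, iso8601_timestamp, svm, wrist`),
#' participant CSV, outcome CSV, the configuration as YAML and a JSON
#' manifest recording the seed and row counts.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$day_compositions, file.path(dir, "day_compositions.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$epochs)) {
    ep <- data.frame(
      participant_id = cohort$epochs$id,
      iso8601_timestamp = format(cohort$epochs$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      svm = cohort$epochs$svm, wrist = cohort$epochs$wrist
    )
    utils::write.csv(ep, file.path(dir, "epochs.csv"), row.names = FALSE)
  }
  cfg <- cohort$config
  cfg_plain <- lapply(unclass(cfg), function(x) if (is.matrix(x)) as.vector(t(x)) else x)
  yaml::write_yaml(cfg_plain, file.path(dir, "config.yaml"))
  manifest <- list(
    seed = cfg$seed,
    n_participants = nrow(cohort$participants),
    n_days = nrow(cohort$day_compositions),
    n_epochs = if (is.null(cohort$epochs)) 0L else nrow(cohort$epochs),
    package_version = as.character(utils::packageVersion("codamove"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
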