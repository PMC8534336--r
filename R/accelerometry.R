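# Epoch-level accelerometer processing: intensity classification, non-wear
# detection, daily summaries, inclusion rules and window averages.

#' Classify epoch magnitudes into intensity classes
#'
#' Half-open cut-point bands partition the non-negative magnitudes:
#' SB below `sb_upper`, LPA in [`sb_upper`, `lpa_upper`), MVPA at or above
#' `lpa_upper`. The LPA lower bound is inclusive so every magnitude falls in
#' exactly one class.
#'
#' @param magnitude Numeric vector of non-negative epoch magnitudes.
#' @param cut_points A [cut_points()] list.
#' @return Factor with levels `SB`, `LPA`, `MVPA`.
#' @export
classify_epoch_intensity <- function(magnitude, cut_points) {
  if (any(!is.finite(magnitude)) || any(magnitude < 0))
    stop("magnitudes must be finite and non-negative")
  cls <- ifelse(magnitude < cut_points$sb_upper, "SB",
         ifelse(magnitude < cut_points$lpa_upper, "LPA", "MVPA"))
  factor(cls, levels = c("SB", "LPA", "MVPA"))
}

#' Detect non-wear time
#'
#' Flags runs of at least `window_minutes` of consecutive zero magnitudes as
#' non-wear; every other epoch is wear.
#'
#' @param series An `epoch_series` data frame (columns `time`, `svm`) with
#'   attribute `epoch_seconds`, or any data frame plus `epoch_seconds`.
#' @param window_minutes Minimum zero-run length counted as non-wear
#'   (default 90 min).
#' @param epoch_seconds Epoch length; taken from the series attribute when
#'   absent.
#' @return Logical vector, `TRUE` for worn epochs.
#' @export
detect_non_wear <- function(series, window_minutes = 90, epoch_seconds = NULL) {
  es <- epoch_seconds %||% attr(series, "epoch_seconds")
  if (is.null(es)) stop("epoch_seconds not given and not an attribute of series")
  if (window_minutes * 60 < es) stop("window must be at least one epoch long")
  check_uniform_spacing(series, es)
  min_run <- ceiling(window_minutes * 60 / es)
  r <- rle(series$svm == 0)
  nonwear <- r$values & r$lengths >= min_run
  !inverse.rle(list(lengths = r$lengths, values = nonwear))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_uniform_spacing <- function(series, epoch_seconds) {
  if (nrow(series) > 1L && "time" %in% names(series)) {
    dt <- diff(as.numeric(series$time))
    if (any(dt <= 0)) stop("epoch times must be strictly increasing")
    if (any(abs(dt - epoch_seconds) > 1e-6))
      stop("epochs must be uniformly spaced at epoch_seconds")
  }
  invisible(TRUE)
}

#' Summarize one day of epochs into behaviour minutes
#'
#' Counts worn epochs per intensity class and converts to minutes; wear time
#' is conserved exactly: SB + LPA + MVPA minutes = wear minutes. Day type is
#' weekend iff the calendar date is a Saturday or Sunday.
#'
#' @param series One day's `epoch_series` for a single participant.
#' @param mask Logical wear mask aligned to `series` (from
#'   [detect_non_wear()]).
#' @param cut_points A [cut_points()] list.
#' @return One-row data frame: `id`, `date`, `day_type`, `wear_min`, `sb`,
#'   `lpa`, `mvpa` (minutes).
#' @export
summarize_day <- function(series, mask, cut_points) {
  if (nrow(series) == 0L) stop("empty epoch series")
  if (length(mask) != nrow(series)) stop("mask must align with series")
  es <- attr(series, "epoch_seconds") %||% stop("series lacks epoch_seconds")
  date <- as.Date(series$time[1L], tz = "UTC")
  worn <- series$svm[mask]
  cls <- classify_epoch_intensity(worn, cut_points)
  counts <- table(cls)
  to_min <- es / 60
  data.frame(
    id = as.character(series$id[1L]),
    date = date,
    day_type = if (format(date, "%u") %in% c("6", "7")) "weekend" else "weekday",
    wear_min = length(worn) * to_min,
    sb = as.numeric(counts[["SB"]]) * to_min,
    lpa = as.numeric(counts[["LPA"]]) * to_min,
    mvpa = as.numeric(counts[["MVPA"]]) * to_min,
    stringsAsFactors = FALSE
  )
}

#' Process an epoch table into day profiles
#'
#' Splits a multi-participant, multi-day epoch table by participant and
#' calendar date, applies non-wear detection and daily summarization.
#'
#' @param epochs `epoch_series` data frame covering any number of
#'   participants and days.
#' @param window_minutes Non-wear window (default 90).
#' @param wrist Wrist placement selecting the cut points; when the table has
#'   a `wrist` column it takes precedence per participant.
#' @return Data frame of day profiles (one row per participant-day).
#' @export
process_epochs <- function(epochs, window_minutes = 90, wrist = "dominant") {
  es <- attr(epochs, "epoch_seconds")
  if (is.null(es)) stop("epochs lack the epoch_seconds attribute")
  key <- paste(epochs$id, as.Date(epochs$time, tz = "UTC"))
  parts <- split(seq_len(nrow(epochs)), key)
  out <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    idx <- parts[[k]]
    day <- epochs[idx, , drop = FALSE]
    attr(day, "epoch_seconds") <- es
    w <- if ("wrist" %in% names(day)) as.character(day$wrist[1L]) else wrist
    mask <- detect_non_wear(day, window_minutes = window_minutes)
    out[[k]] <- summarize_day(day, mask, cut_points(w))
  }
  profiles <- do.call(rbind, out)
  profiles[order(profiles$id, profiles$date), , drop = FALSE]
}

#' Apply wear-time inclusion rules
#'
#' A day is valid if wear time reaches `min_wear_hours`; a participant is
#' retained if they have at least `min_days` valid days of which at least
#' `min_weekend_days` fall on a weekend. Excluded participants get a logged
#' reason naming the first failed rule.
#'
#' @param profiles Day-profile data frame from [process_epochs()].
#' @param min_days Minimum valid days (default 3).
#' @param min_weekend_days Minimum valid weekend days (default 1).
#' @param min_wear_hours Minimum daily wear in hours (default 6).
#' @return List with `retained` (character ids), `valid_profiles` (valid
#'   days of retained participants) and `exclusions` (data frame `id`,
#'   `reason`).
#' @export
filter_valid_participants <- function(profiles, min_days = 3,
                                      min_weekend_days = 1,
                                      min_wear_hours = 6) {
  if (is.null(profiles) || nrow(profiles) == 0L)
    return(list(retained = character(0),
                valid_profiles = profiles,
                exclusions = data.frame(id = character(0), reason = character(0))))
  valid <- profiles$wear_min >= min_wear_hours * 60
  ids <- sort(unique(profiles$id))
  retained <- character(0)
  excl <- list()
  for (pid in ids) {
    rows <- profiles$id == pid & valid
    n_valid <- sum(rows)
    n_wkend <- sum(rows & profiles$day_type == "weekend")
    if (n_valid < min_days) {
      excl[[pid]] <- sprintf("only %d valid day(s); %d required", n_valid, min_days)
    } else if (n_wkend < min_weekend_days) {
      excl[[pid]] <- sprintf("only %d valid weekend day(s); %d required",
                             n_wkend, min_weekend_days)
    } else {
      retained <- c(retained, pid)
    }
  }
  list(
    retained = retained,
    valid_profiles = profiles[valid & profiles$id %in% retained, , drop = FALSE],
    exclusions = data.frame(id = names(excl),
                            reason = unlist(excl, use.names = FALSE),
                            stringsAsFactors = FALSE)
  )
}

#' Per-participant window mean minutes
#'
#' Arithmetic mean of daily SB/LPA/MVPA minutes over the valid days matching
#' the window: `week` = weekdays, `weekend` = weekend days, `four_day` = all
#' valid days. Participants with no matching day are dropped with a warning.
#'
#' @param profiles Valid day profiles (see [filter_valid_participants()]).
#' @param window One of `"week"`, `"weekend"`, `"four_day"`.
#' @return Data frame `id`, `sb`, `lpa`, `mvpa`, `n_days`.
#' @export
derive_window_minutes <- function(profiles, window = c("week", "weekend", "four_day")) {
  window <- match.arg(window)
  sel <- switch(window,
    week = profiles$day_type == "weekday",
    weekend = profiles$day_type == "weekend",
    four_day = rep(TRUE, nrow(profiles))
  )
  sub <- profiles[sel, , drop = FALSE]
  dropped <- setdiff(unique(profiles$id), unique(sub$id))
  if (length(dropped))
    warning("no ", window, " days for participant(s): ",
            paste(dropped, collapse = ", "), "; dropped from this window")
  if (nrow(sub) == 0L)
    return(data.frame(id = character(0), sb = numeric(0), lpa = numeric(0),
                      mvpa = numeric(0), n_days = integer(0)))
  agg <- stats::aggregate(sub[, c("sb", "lpa", "mvpa")],
                          by = list(id = sub$id), FUN = mean)
  agg$n_days <- as.integer(table(sub$id)[agg$id])
  agg
}

#' Classify guideline adherence
#'
#' Sufficiently active iff mean daily physical activity (LPA + MVPA) over the
#' valid days reaches 180 min, the UK recommendation for under-5s.
#'
#' @param profiles Valid day profiles for one participant (>= 1 row).
#' @param threshold_minutes Daily PA recommendation (default 180).
#' @return `"sufficiently_active"` or `"insufficiently_active"`.
#' @export
classify_guideline <- function(profiles, threshold_minutes = 180) {
  if (is.null(profiles) || nrow(profiles) == 0L)
    stop("no valid days to classify")
  pa <- mean(profiles$lpa + profiles$mvpa)
  if (pa >= threshold_minutes) "sufficiently_active" else "insufficiently_active"
}

#' Read an epoch CSV
#'
#' Columns `participant_id`, `iso8601_timestamp`, `svm`, `wrist`; epoch
#' length is inferred from the timestamp spacing.
#'
#' @param path CSV file path.
#' @return An `epoch_series` data frame.
#' @export
read_epochs_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "iso8601_timestamp", "svm", "wrist")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("epoch CSV missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(
    id = as.character(d$participant_id),
    time = as.POSIXct(d$iso8601_timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    svm = d$svm, wrist = d$wrist, stringsAsFactors = FALSE
  )
  es <- unique(round(diff(as.numeric(out$time[out$id == out$id[1L]][1:3]))))
  attr(out, "epoch_seconds") <- as.integer(es[1L])
  class(out) <- c("epoch_series", "data.frame")
  out
}
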