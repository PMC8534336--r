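#' Published calibration summaries for UK preschool movement behaviour
#'
#' Descriptive statistics from an observational cohort of British preschool
#' children (3-4 years, wrist-worn accelerometry) that the synthetic-cohort
#' generator is calibrated to: geometric-mean minutes per day in SB, LPA and
#' MVPA for week-, weekend- and 4-day-derived windows (each closed to a
#' 600-min bounded day), and the corresponding pairwise log-ratio variation
#' matrices. These are generator defaults, not hard-coded model constants;
#' any element can be overridden through [generator_config()].
#'
#' @return A list with elements `minutes` (list of named length-3 vectors
#'   `week`, `weekend`, `four_day`, in min/day) and `variation` (list of
#'   3 x 3 variation matrices for the same windows).
#' @export
movement_calibration <- function() {
  parts <- behaviour_parts()
  mk_min <- function(v) stats::setNames(v, parts)
  mk_var <- function(sl, sm, lmv) {
    m <- matrix(0, 3, 3, dimnames = list(parts, parts))
    m["sb", "lpa"] <- m["lpa", "sb"] <- sl
    m["sb", "mvpa"] <- m["mvpa", "sb"] <- sm
    m["lpa", "mvpa"] <- m["mvpa", "lpa"] <- lmv
    m
  }
  list(
    minutes = list(
      week     = mk_min(c(559.72, 6.57, 33.71)),
      weekend  = mk_min(c(586.80, 4.60, 8.60)),
      four_day = mk_min(c(570.99, 5.78, 23.23))
    ),
    variation = list(
      week     = mk_var(0.36, 0.22, 0.52),
      weekend  = mk_var(0.49, 0.93, 0.99),
      four_day = mk_var(0.30, 0.23, 0.53)
    )
  )
}

#' Wrist accelerometer cut points for 3-4-year-olds
#'
#' Signal-vector-magnitude thresholds separating sedentary behaviour, light
#' activity and moderate-to-vigorous activity for wrist-worn accelerometry in
#' preschoolers, by wrist placement. SB is below `sb_upper`; LPA is
#' [`sb_upper`, `lpa_upper`); MVPA is at or above `lpa_upper`. Thresholds are
#' applied on whatever magnitude scale the epoch values are declared in.
#'
#' @param wrist `"dominant"` or `"non_dominant"`.
#' @return List with `wrist`, `sb_upper`, `lpa_upper`.
#' @export
cut_points <- function(wrist = c("dominant", "non_dominant")) {
  wrist <- match.arg(wrist)
  cp <- switch(wrist,
    dominant     = list(sb_upper = 8.1, lpa_upper = 9.3),
    non_dominant = list(sb_upper = 5.3, lpa_upper = 8.6)
  )
  c(list(wrist = wrist), cp)
}
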