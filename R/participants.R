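# Anthropometrics and covariate encoding.

#' Body mass index
#'
#' @param mass Body mass in kg.
#' @param height Standing height in m.
#' @return BMI in kg/m^2.
#' @examples compute_bmi(16, 1.0)
#' @export
compute_bmi <- function(mass, height) {
  if (any(!is.finite(mass)) || any(!is.finite(height)) ||
      any(mass <= 0) || any(height <= 0))
    stop("mass and height must be positive")
  mass / height^2
}

# Look up cut values for one (age, sex) from a reference table with columns
# (age_years, sex, cut_name, value); nearest whole-age match, no LMS
# interpolation.
lookup_cuts <- function(reference_table, age, sex, cut_names) {
  req <- c("age_years", "sex", "cut_name", "value")
  if (!all(req %in% names(reference_table)))
    stop("reference_table needs columns ", paste(req, collapse = ", "))
  rows <- reference_table[reference_table$sex == sex, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no reference rows for sex '", sex, "'")
  nearest <- rows$age_years[which.min(abs(rows$age_years - age))]
  rows <- rows[rows$age_years == nearest, , drop = FALSE]
  vals <- stats::setNames(rep(NA_real_, length(cut_names)), cut_names)
  for (cn in cut_names) {
    hit <- rows$value[rows$cut_name == cn]
    if (length(hit) != 1L)
      stop("reference table missing cut '", cn, "' for age ", age, ", sex ", sex)
    vals[[cn]] <- hit
  }
  vals
}

#' Classify weight status from BMI against a reference chart
#'
#' Overweight if BMI is at or above the 95th-percentile value for the
#' child's (age, sex) in the supplied chart; the boundary is inclusive.
#'
#' @param bmi BMI in kg/m^2.
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @param reference_table Data frame with columns `age_years`, `sex`,
#'   `cut_name` (must contain `"p95"`), `value`. Reference charts are
#'   user-supplied; none is embedded.
#' @return `"overweight"` or `"normal"`.
#' @export
classify_bmi_status <- function(bmi, age, sex, reference_table) {
  p95 <- lookup_cuts(reference_table, age, sex, "p95")[["p95"]]
  if (bmi >= p95) "overweight" else "normal"
}

#' Classify weight status from waist circumference
#'
#' Three categories against two user-supplied cuts per (age, sex):
#' underweight below `wc_lower`, overweight/obese at or above `wc_upper`,
#' normal in between.
#'
#' @param wc Waist circumference in cm.
#' @inheritParams classify_bmi_status
#' @param reference_table Chart with `cut_name` values `"wc_lower"` and
#'   `"wc_upper"`.
#' @return One of `"underweight"`, `"normal"`, `"overweight/obese"`.
#' @export
classify_wc_status <- function(wc, age, sex, reference_table) {
  cuts <- lookup_cuts(reference_table, age, sex, c("wc_lower", "wc_upper"))
  if (cuts[["wc_lower"]] >= cuts[["wc_upper"]])
    stop("reference cuts out of order: wc_lower >= wc_upper")
  if (wc < cuts[["wc_lower"]]) "underweight"
  else if (wc >= cuts[["wc_upper"]]) "overweight/obese"
  else "normal"
}

#' Encode regression covariates
#'
#' Builds the (age, bmi, sex) covariate matrix used by the ilr regression
#' models. Sex is coded female = 0, male = 1; continuous covariates are
#' passed through unstandardized.
#'
#' @param participants Data frame with columns `id`, `age`, `bmi`, `sex`.
#' @return Numeric matrix with columns `age`, `bmi`, `sex`, one row per
#'   participant, rownames = ids.
#' @export
encode_covariates <- function(participants) {
  req <- c("id", "age", "bmi", "sex")
  miss <- setdiff(req, names(participants))
  if (length(miss)) stop("participants missing columns: ", paste(miss, collapse = ", "))
  for (col in c("age", "bmi", "sex")) {
    bad <- is.na(participants[[col]])
    if (any(bad))
      stop("missing ", col, " for participant(s) ",
           paste(participants$id[bad], collapse = ", "))
  }
  if (!all(participants$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  m <- cbind(age = participants$age, bmi = participants$bmi,
             sex = as.numeric(participants$sex == "male"))
  rownames(m) <- participants$id
  m
}

#' Read a participant CSV
#'
#' Expects columns `id`, `age`, `sex`, `height`, `mass` (and optionally
#' `bmi`, `waist_circumference`); BMI is recomputed from mass and height and
#' checked against any supplied value.
#'
#' @param path CSV file path.
#' @return Participant data frame with a consistent `bmi` column.
#' @export
read_participants_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "age", "sex", "height", "mass")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("participant CSV missing columns: ", paste(miss, collapse = ", "))
  bmi <- compute_bmi(d$mass, d$height)
  if ("bmi" %in% names(d) && any(abs(d$bmi - bmi) > 1e-6 * pmax(1, bmi)))
    stop("supplied bmi inconsistent with mass/height^2")
  d$bmi <- bmi
  d
}
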