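# Scoring of the adapted twelve-skill gross motor battery (TGMD-2 based,
# skip added, underhand roll removed) and rater agreement.

#' Skill battery definition
#'
#' The adapted twelve-skill battery: seven locomotor skills (run, gallop,
#' hop, leap, horizontal jump, skip, slide) and five object-control skills
#' (strike, bounce, catch, kick, throw). Each skill is scored per trial;
#' leap, skip and bounce carry a per-trial maximum of 3, every other skill 4,
#' and each skill is attempted twice.
#'
#' @param adapted Logical; `FALSE` gives the unmodified TGMD-2 battery
#'   (no skip, underhand roll restored to object control, max 4).
#' @return Data frame with columns `skill`, `subset`, `max_per_trial`.
#' @export
skill_battery <- function(adapted = TRUE) {
  if (adapted) {
    data.frame(
      skill = c("run", "gallop", "hop", "leap", "horizontal_jump", "skip",
                "slide", "strike", "bounce", "catch", "kick", "throw"),
      subset = c(rep("locomotor", 7), rep("object_control", 5)),
      max_per_trial = c(4, 4, 4, 3, 4, 3, 4, 4, 3, 4, 4, 4),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      skill = c("run", "gallop", "hop", "leap", "horizontal_jump", "slide",
                "strike", "bounce", "catch", "kick", "throw", "underhand_roll"),
      subset = c(rep("locomotor", 6), rep("object_control", 6)),
      max_per_trial = c(4, 4, 4, 3, 4, 4, 4, 3, 4, 4, 4, 4),
      stringsAsFactors = FALSE
    )
  }
}

# Validate a score sheet: data frame with columns skill, trial1, trial2.
check_sheet <- function(sheet, battery) {
  req <- c("skill", "trial1", "trial2")
  miss <- setdiff(req, names(sheet))
  if (length(miss)) stop("score sheet missing columns: ", paste(miss, collapse = ", "))
  absent <- setdiff(battery$skill, sheet$skill)
  if (length(absent)) stop("score sheet missing skill(s): ", paste(absent, collapse = ", "))
  m <- merge(sheet, battery, by = "skill")
  for (tr in c("trial1", "trial2")) {
    s <- m[[tr]]
    if (any(is.na(s)) || any(s != round(s)) || any(s < 0))
      stop(tr, " scores must be non-negative integers")
    over <- s > m$max_per_trial
    if (any(over))
      stop("score exceeds per-trial maximum for skill(s): ",
           paste(m$skill[over], collapse = ", "))
  }
  m
}

#' Two-trial total for one skill
#'
#' @param sheet Score sheet data frame (`skill`, `trial1`, `trial2`).
#' @param skill Skill name.
#' @param battery Battery definition from [skill_battery()].
#' @return Integer trial1 + trial2.
#' @export
skill_total <- function(sheet, skill, battery = skill_battery()) {
  m <- check_sheet(sheet, battery)
  row <- m[m$skill == skill, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown or duplicated skill: ", skill)
  as.integer(row$trial1 + row$trial2)
}

#' Subset and total motor-competence scores
#'
#' Sums two-trial skill totals into the locomotor and object-control subset
#' scores; total motor competence is their sum. With the default battery the
#' bounds are locomotor 0-52, object control 0-38, total 0-90.
#'
#' @inheritParams skill_total
#' @return Named numeric `(locomotor, object_control, total)`.
#' @export
subset_scores <- function(sheet, battery = skill_battery()) {
  m <- check_sheet(sheet, battery)
  tot <- m$trial1 + m$trial2
  loco <- sum(tot[m$subset == "locomotor"])
  obj <- sum(tot[m$subset == "object_control"])
  c(locomotor = loco, object_control = obj, total = loco + obj)
}

#' Percent agreement between two raters
#'
#' Proportion of exactly matching per-trial scores across aligned sheets,
#' overall and per skill. Sheets must cover the same participants and
#' skills; the measure is symmetric in the raters.
#'
#' @param rater_a,rater_b Data frames with columns `participant_id`,
#'   `skill`, `trial`, `score`.
#' @return List with `overall` (percent) and `per_skill` (named percents).
#' @export
percent_agreement <- function(rater_a, rater_b) {
  req <- c("participant_id", "skill", "trial", "score")
  for (d in list(rater_a, rater_b)) {
    miss <- setdiff(req, names(d))
    if (length(miss)) stop("rater sheet missing columns: ", paste(miss, collapse = ", "))
  }
  key <- function(d) paste(d$participant_id, d$skill, d$trial, sep = "\r")
  a <- rater_a[order(key(rater_a)), , drop = FALSE]
  b <- rater_b[order(key(rater_b)), , drop = FALSE]
  if (nrow(a) != nrow(b) || !identical(key(a), key(b)))
    stop("rater sheets are misaligned: participants/skills/trials differ")
  match_ <- a$score == b$score
  per_skill <- vapply(split(match_, a$skill), function(x) 100 * mean(x), numeric(1))
  list(overall = 100 * mean(match_), per_skill = per_skill)
}

#' Read a long-format score-sheet CSV
#'
#' Columns `participant_id`, `skill`, `trial` (1 or 2), `score`; returns one
#' wide sheet per participant.
#'
#' @param path CSV file path.
#' @return Named list of score sheets (`skill`, `trial1`, `trial2`).
#' @export
read_score_sheets_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "skill", "trial", "score")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("score CSV missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(split(d, d$participant_id), function(p) {
    w <- stats::reshape(p[, c("skill", "trial", "score")], idvar = "skill",
                        timevar = "trial", direction = "wide")
    names(w) <- sub("^score\\.", "trial", names(w))
    w
  })
  out
}
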