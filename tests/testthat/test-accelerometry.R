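# Epoch classification, non-wear detection, daily summaries, inclusion
# rules and window means.

make_series <- function(svm, date = "2016-06-02", id = "P01",
                        epoch_seconds = 10, wrist = "dominant") {
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  s <- data.frame(id = id,
                  time = t0 + seq(0, by = epoch_seconds, length.out = length(svm)),
                  svm = svm, wrist = wrist, stringsAsFactors = FALSE)
  attr(s, "epoch_seconds") <- epoch_seconds
  class(s) <- c("epoch_series", "data.frame")
  s
}

test_that("cut points partition magnitudes with half-open bands", {
  cp_d <- cut_points("dominant")
  expect_equal(as.character(classify_epoch_intensity(7.0, cp_d)), "SB")
  expect_equal(as.character(classify_epoch_intensity(8.1, cp_d)), "LPA")  # lower bound inclusive
  expect_equal(as.character(classify_epoch_intensity(9.3, cp_d)), "MVPA")
  cp_n <- cut_points("non_dominant")
  expect_equal(as.character(classify_epoch_intensity(8.6, cp_n)), "MVPA")
  expect_equal(as.character(classify_epoch_intensity(5.2, cp_n)), "SB")
  # every non-negative magnitude maps to exactly one class, monotonically
  mags <- seq(0, 20, by = 0.1)
  cls <- classify_epoch_intensity(mags, cp_d)
  expect_false(anyNA(cls))
  expect_true(all(diff(as.integer(cls)) >= 0))
  expect_error(classify_epoch_intensity(-1, cp_d), "non-negative")
})

test_that("non-wear detection flags only zero runs of at least the window", {
  s_all0 <- make_series(rep(0, 8640))
  expect_true(all(!detect_non_wear(s_all0)))  # whole day non-wear
  # 89 min of zeros flanked by activity stays wear
  s89 <- make_series(c(rep(10, 60), rep(0, 89 * 6), rep(10, 60)))
  expect_true(all(detect_non_wear(s89)))
  # constructed 120-min zero block is exactly what gets flagged
  block <- rep(0, 120 * 6)
  s120 <- make_series(c(rep(10, 300), block, rep(10, 300)))
  mask <- detect_non_wear(s120)
  expect_equal(which(!mask), 300 + seq_along(block))
  expect_error(detect_non_wear(s89, window_minutes = 0.1), "at least one epoch")
})

test_that("daily summaries conserve wear time and type days correctly", {
  cp <- cut_points("dominant")
  s <- make_series(rep(5, 8640))  # all SB, no non-wear
  d <- summarize_day(s, detect_non_wear(s), cp)
  expect_equal(d$sb, 1440)
  expect_equal(d$lpa + d$mvpa, 0)
  expect_equal(d$day_type, "weekday")  # 2016-06-02 is a Thursday
  d_sat <- summarize_day(make_series(rep(5, 8640), date = "2016-06-04"),
                         rep(TRUE, 8640), cp)
  expect_equal(d_sat$day_type, "weekend")
  # entirely non-wear day: zero wear, zero minutes
  s0 <- make_series(rep(0, 8640))
  d0 <- summarize_day(s0, detect_non_wear(s0), cp)
  expect_equal(d0$wear_min, 0)
  expect_equal(d0$sb + d0$lpa + d0$mvpa, 0)
  # conservation on a mixed day
  set.seed(2)
  sm <- make_series(sample(c(3, 8.5, 12), 8640, replace = TRUE))
  dm <- summarize_day(sm, rep(TRUE, 8640), cp)
  expect_equal(dm$sb + dm$lpa + dm$mvpa, dm$wear_min)
  expect_error(summarize_day(sm[0, ], logical(0), cp), "empty")
})

test_that("rendered synthetic days round-trip through summarization", {
  cfg <- generator_config(n_participants = 1, seed = 5,
                          nonwear_block_minutes = 120)
  comp <- c(sb = 500, lpa = 40, mvpa = 60)
  s <- render_epoch_series(comp, cfg, seed = 5)
  expect_equal(nrow(s), 8640)  # 10-s epochs over 24 h
  mask <- detect_non_wear(s)
  d <- summarize_day(s, mask, cut_points("dominant"))
  # recovers generator minutes within one epoch (1/6 min) per class
  expect_lt(abs(d$sb - comp[["sb"]]), 1 / 6 + 1e-9)
  expect_lt(abs(d$lpa - comp[["lpa"]]), 1 / 6 + 1e-9)
  expect_lt(abs(d$mvpa - comp[["mvpa"]]), 1 / 6 + 1e-9)
  expect_equal(d$wear_min, 600)
  # the inserted 120-min block is flagged: non-wear epochs inside the worn
  # period total exactly 120 min
  worn_start <- min(which(s$svm > 0))
  inner <- !mask[worn_start:length(mask)]
  expect_equal(sum(inner) / 6, 120)
  # degenerate near-pure composition survives the round trip
  s2 <- render_epoch_series(c(590, 5, 5), generator_config(n_participants = 1),
                            seed = 6)
  d2 <- summarize_day(s2, detect_non_wear(s2), cut_points("dominant"))
  expect_lt(abs(d2$sb - 590), 1 / 6 + 1e-9)
  expect_lt(abs(d2$lpa - 5), 1 / 6 + 1e-9)
  expect_lt(abs(d2$mvpa - 5), 1 / 6 + 1e-9)
  expect_error(render_epoch_series(c(1400, 30, 30),
                                   generator_config(n_participants = 1,
                                                    nonwear_block_minutes = 120),
                                   seed = 1),
               "exceeds")
})

test_that("inclusion rules retain 7 of 10 planted participants with reasons", {
  profiles <- fixture_day_profiles()
  res <- filter_valid_participants(profiles)
  expect_equal(length(res$retained), 7L)
  expect_setequal(res$exclusions$id, c("P02", "P05", "P09"))
  expect_match(res$exclusions$reason[res$exclusions$id == "P02"], "valid day")
  expect_match(res$exclusions$reason[res$exclusions$id == "P05"], "weekend")
  expect_match(res$exclusions$reason[res$exclusions$id == "P09"], "valid day")
  # 2 valid weekdays + 1 valid weekend day is enough
  p <- profiles[profiles$id == "P01", ][1:3, ]
  keep <- filter_valid_participants(p)
  expect_equal(keep$retained, "P01")
  # 4 valid weekdays but no weekend day is not
  p4 <- profiles[profiles$id == "P01", ]
  p4$day_type <- "weekday"
  expect_equal(nrow(filter_valid_participants(p4)$exclusions), 1L)
  # idempotent and order-independent
  again <- filter_valid_participants(res$valid_profiles)
  expect_equal(again$retained, res$retained)
  shuffled <- profiles[rev(seq_len(nrow(profiles))), ]
  expect_equal(filter_valid_participants(shuffled)$retained, res$retained)
  # empty input is empty output, not an error
  expect_equal(filter_valid_participants(profiles[0, ])$retained, character(0))
})

test_that("window means average matching days arithmetically", {
  profiles <- fixture_day_profiles()
  one <- profiles[profiles$id == "P01", ]
  one[1, c("sb", "lpa", "mvpa")] <- c(500, 10, 30)
  one[2, c("sb", "lpa", "mvpa")] <- c(520, 14, 36)
  wk <- derive_window_minutes(one, "week")
  expect_equal(unname(unlist(wk[1, c("sb", "lpa", "mvpa")])), c(510, 12, 33))
  # a single weekend day is its own mean
  wkend <- derive_window_minutes(one[3, , drop = FALSE], "weekend")
  expect_equal(wkend$sb, one$sb[3])
  # four_day covers all valid days
  all4 <- derive_window_minutes(one, "four_day")
  expect_equal(all4$n_days, 4L)
  # participants without matching days are dropped with a warning
  expect_warning(derive_window_minutes(one[1:2, ], "weekend"), "dropped")
})

test_that("guideline classification splits at 180 min of daily PA", {
  p <- fixture_day_profiles()[1:3, ]
  p$lpa <- c(100, 100, 100); p$mvpa <- c(90, 90, 90)
  expect_equal(classify_guideline(p), "sufficiently_active")
  p$mvpa <- c(79.9, 79.9, 79.9)
  expect_equal(classify_guideline(p), "insufficiently_active")
  # the sample-mean week composition (about 40 min of PA) falls well short
  calib <- movement_calibration()$minutes$week
  one <- data.frame(id = "x", date = as.Date("2016-06-02"),
                    day_type = "weekday", wear_min = 600,
                    sb = calib[["sb"]], lpa = calib[["lpa"]],
                    mvpa = calib[["mvpa"]])
  expect_equal(classify_guideline(one), "insufficiently_active")
  expect_error(classify_guideline(one[0, ]), "no valid days")
})
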