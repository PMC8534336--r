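# Shared fixture builders.

# Small compositional sample with hand-controllable structure.
fixture_compositions <- function(n = 10, seed = 42) {
  set.seed(seed)
  m <- cbind(sb = exp(rnorm(n, log(550), 0.2)),
             lpa = exp(rnorm(n, log(7), 0.4)),
             mvpa = exp(rnorm(n, log(30), 0.5)))
  m
}

# Simulate one correctly-specified regression dataset and return the pieces.
fixture_regression <- function(n = 200, seed = 1, beta = NULL, noise = NULL,
                               day_type = "weekday") {
  cfg <- generator_config(n_participants = n, seed = seed, days = day_type)
  if (!is.null(beta) || !is.null(noise)) {
    tb <- cfg$true_beta
    if (!is.null(beta)) tb$total_mc <- setNames(beta, names(tb$total_mc))
    ns <- cfg$noise_sd
    if (!is.null(noise)) ns[["total_mc"]] <- noise
    cfg <- generator_config(n_participants = n, seed = seed, days = day_type,
                            true_beta = tb, noise_sd = ns)
  }
  p <- generate_participants(cfg)
  dc <- generate_day_compositions(cfg, p)
  comp <- as.matrix(dc[, c("sb", "lpa", "mvpa")])
  fms <- generate_fms_outcomes(comp, p, cfg)
  list(config = cfg, participants = p, comp = comp,
       z = ilr_transform(comp), covariates = encode_covariates(p),
       y = fms$outcomes$total_mc, truth = fms$truth)
}

# Ten-participant day-profile fixture with three planted inclusion-rule
# violations: P02 has too few valid days (one day under the 6-h wear floor),
# P05 has no valid weekend day, P09 wore the device only twice.
fixture_day_profiles <- function() {
  mk <- function(id, date, day_type, wear, sb, lpa, mvpa) {
    data.frame(id = id, date = as.Date(date), day_type = day_type,
               wear_min = wear, sb = sb, lpa = lpa, mvpa = mvpa,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  dates <- c("2016-06-02", "2016-06-03", "2016-06-04", "2016-06-05")
  types <- c("weekday", "weekday", "weekend", "weekend")
  for (i in 1:10) {
    id <- sprintf("P%02d", i)
    wear <- rep(600, 4)
    dates_i <- dates
    types_i <- types
    if (id == "P02") wear <- c(600, 200, 200, 600)   # only 2 valid days
    if (id == "P05") {                               # 3 valid days, no weekend
      dates_i <- c("2016-06-01", dates)
      types_i <- c("weekday", types)
      wear <- c(600, 600, 600, 100, 100)
    }
    if (id == "P09") wear <- c(600, 600, 0, 0)       # only 2 days worn
    for (d in seq_along(wear)) {
      if (wear[d] == 0) next
      rows[[length(rows) + 1L]] <-
        mk(id, dates_i[d], types_i[d], wear[d],
           sb = wear[d] * 0.9, lpa = wear[d] * 0.02, mvpa = wear[d] * 0.08)
    }
  }
  do.call(rbind, rows)
}
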