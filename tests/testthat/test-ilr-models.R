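# ilr regression, composition Wald test, diagnostics, naive regressions and
# isotemporal substitution.

test_that("zero-noise synthetic data recover the true coefficients exactly", {
  d <- fixture_regression(n = 120, seed = 21, noise = 1e-12,
                          day_type = "weekday")
  f <- fit_ilr_regression(d$y, d$z, d$covariates, outcome = "total_mc")
  truth <- d$config$true_beta$total_mc
  expect_equal(unname(f$coefficients), unname(truth), tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  # permuting row order leaves the fit unchanged
  set.seed(1); ord <- sample(length(d$y))
  f2 <- fit_ilr_regression(d$y[ord], d$z[ord, ], d$covariates[ord, ])
  expect_equal(unname(f2$coefficients), unname(f$coefficients), tolerance = 1e-9)
})

test_that("fit validation catches collinearity and missing data", {
  d <- fixture_regression(n = 50, seed = 22)
  cov_bad <- cbind(d$covariates, dup = d$covariates[, "age"])
  expect_error(fit_ilr_regression(d$y, d$z, cov_bad), "collinear")
  y <- d$y; y[1] <- NA
  expect_error(fit_ilr_regression(y, d$z, d$covariates), "missing")
  expect_error(fit_ilr_regression(d$y[1:5], d$z[1:5, ], d$covariates[1:5, ]),
               "more observations")
})

test_that("composition Wald test matches the type-II Wald oracle", {
  skip_if_not_installed("car")
  d <- fixture_regression(n = 150, seed = 23)
  f <- fit_ilr_regression(d$y, d$z, d$covariates)
  w <- composition_wald_test(f)
  # independent oracle: joint 2-df Wald via the general linear hypothesis
  lh <- car::linearHypothesis(f$lm, c("z1 = 0", "z2 = 0"), test = "Chisq")
  expect_equal(w$statistic, lh$Chisq[2], tolerance = 1e-8)
  expect_equal(w$p_value, lh$`Pr(>Chisq)`[2], tolerance = 1e-8)
  expect_equal(w$df, 2L)
})

test_that("Wald statistic is zero with zero compositional coefficients", {
  d <- fixture_regression(n = 80, seed = 24)
  f <- fit_ilr_regression(d$y, d$z, d$covariates)
  f$coefficients[c("z1", "z2")] <- 0
  w <- composition_wald_test(f)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
})

test_that("regression summaries are invariant to the ilr basis", {
  d <- fixture_regression(n = 150, seed = 25)
  V2 <- alternative_sbp()
  z_alt <- ilr_transform(d$comp, basis = ilr_basis(V2))
  f1 <- fit_ilr_regression(d$y, d$z, d$covariates, basis = ilr_basis())
  f2 <- fit_ilr_regression(d$y, z_alt, d$covariates, basis = ilr_basis(V2))
  expect_equal(f1$r2, f2$r2, tolerance = 1e-10)
  expect_equal(f1$r2_composition, f2$r2_composition, tolerance = 1e-10)
  expect_equal(composition_wald_test(f1)$statistic,
               composition_wald_test(f2)$statistic, tolerance = 1e-8)
  base <- geometric_mean_composition(d$comp)
  for (pair in list(c("lpa", "sb"), c("mvpa", "lpa"), c("sb", "mvpa"))) {
    r1 <- predict_reallocation_difference(f1, base, pair[1], pair[2], 5)
    r2 <- predict_reallocation_difference(f2, base, pair[1], pair[2], 5)
    expect_equal(r1$estimate, r2$estimate, tolerance = 1e-8)
    expect_equal(r1$se, r2$se, tolerance = 1e-8)
  }
})

test_that("naive single-behaviour regression reports standardized B", {
  set.seed(26)
  n <- 400
  cv <- cbind(age = runif(n, 3, 4), bmi = rnorm(n, 16, 1.4),
              sex = rbinom(n, 1, 0.5))
  minutes <- runif(n, 400, 600)
  y <- rnorm(n)  # unrelated outcome
  f <- fit_single_behaviour_regression(y, minutes, cv)
  expect_lt(abs(f$B), 0.15)  # null case
  expect_true(f$ci[1] <= f$B && f$B <= f$ci[2])
  # standardized B is invariant to a unit change (minutes -> hours)
  y2 <- minutes * 0.01 + rnorm(n)
  fa <- fit_single_behaviour_regression(y2, minutes, cv)
  fb <- fit_single_behaviour_regression(y2, minutes / 60, cv)
  expect_equal(fa$B, fb$B, tolerance = 1e-10)
  # duplicating every row keeps B, narrows the CI
  idx <- rep(seq_len(n), 2)
  fd <- fit_single_behaviour_regression(y2[idx], minutes[idx], cv[idx, ])
  expect_equal(fd$B, fa$B, tolerance = 1e-10)
  expect_lt(diff(fd$ci), diff(fa$ci))
  expect_error(fit_single_behaviour_regression(y, rep(5, n), cv),
               "zero variance")
})

test_that("diagnostics flag planted outliers and stay quiet on clean fits", {
  d <- fixture_regression(n = 120, seed = 27, noise = 1e-9)
  f <- fit_ilr_regression(d$y, d$z, d$covariates)
  clean <- run_diagnostics(f)
  expect_equal(clean$n_flagged, 0L)
  y_out <- d$y
  y_out[17] <- y_out[17] + 10 * sd(d$truth$noise$total_mc) + 50
  f_out <- fit_ilr_regression(y_out, d$z, d$covariates)
  dg <- run_diagnostics(f_out)
  expect_true(17 %in% dg$outliers)
  expect_true(is.finite(dg$normality$statistic))
  expect_true(is.finite(dg$heteroscedasticity$statistic))
})

test_that("reallocation prediction equals the direct-prediction oracle", {
  d <- fixture_regression(n = 150, seed = 28)
  f <- fit_ilr_regression(d$y, d$z, d$covariates)
  base <- geometric_mean_composition(d$comp)
  for (pair in list(c("lpa", "sb"), c("mvpa", "sb"), c("sb", "mvpa"))) {
    r <- predict_reallocation_difference(f, base, pair[1], pair[2], 5)
    # oracle: full-model prediction difference with covariates held fixed
    z0 <- ilr_transform(base)
    z1 <- ilr_transform(reallocate(base, pair[1], pair[2], 5))
    newd <- data.frame(z1 = c(z0[1], z1[1]), z2 = c(z0[2], z1[2]),
                       age = 3.5, bmi = 16, sex = 1)
    pred <- predict(f$lm, newdata = newd)
    expect_equal(r$estimate, unname(pred[2] - pred[1]), tolerance = 1e-9)
  }
  # delta = 0 pins the estimate and CI at zero
  r0 <- predict_reallocation_difference(f, base, "lpa", "sb", 0)
  expect_equal(r0$estimate, 0)
  expect_equal(c(r0$ci_low, r0$ci_high), c(0, 0))
  # asymmetry of the ilr construction: +5 A -5 B is not minus (+5 B -5 A)
  fwd <- predict_reallocation_difference(f, base, "lpa", "sb", 5)
  rev <- predict_reallocation_difference(f, base, "sb", "lpa", 5)
  expect_gt(abs(fwd$estimate + rev$estimate), 1e-6)
})

test_that("isotemporal table covers all six ordered pairs per outcome", {
  d <- fixture_regression(n = 150, seed = 29)
  fits <- list(
    total_mc = fit_ilr_regression(d$y, d$z, d$covariates, outcome = "total_mc"))
  base <- geometric_mean_composition(d$comp)
  tab <- isotemporal_table(fits, base, delta = 5)
  expect_equal(nrow(tab), 6L)
  expect_equal(sum(duplicated(tab[, c("add", "remove")])), 0L)
  expect_true(all(tab$ci_low <= tab$estimate & tab$estimate <= tab$ci_high))
  # cell-by-cell agreement with the per-pair call
  for (k in seq_len(nrow(tab))) {
    one <- predict_reallocation_difference(fits$total_mc, base,
                                           tab$add[k], tab$remove[k], 5)
    expect_equal(tab$estimate[k], one$estimate, tolerance = 1e-12)
  }
  # an infeasible cell goes NA with a note, other cells intact
  tiny <- c(sb = 592, lpa = 3, mvpa = 5)
  tab2 <- isotemporal_table(fits, tiny, delta = 5, method = "exact")
  bad <- is.na(tab2$estimate)
  expect_true(any(bad) && any(!bad))
  expect_true(all(grepl("infeasible", tab2$note[bad])))
  # clamp route leaves every cell estimable
  tab3 <- isotemporal_table(fits, tiny, delta = 5, method = "clamp")
  expect_false(anyNA(tab3$estimate))
})
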