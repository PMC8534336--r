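# Regression of motor-competence outcomes on ilr coordinates plus
# covariates, joint Wald testing of the composition block, diagnostics,
# naive per-behaviour regressions, and isotemporal substitution.

#' Fit an ilr multiple linear regression
#'
#' Ordinary least squares of an outcome on the two ilr coordinates of the
#' behaviour composition plus (age, bmi, sex) covariates, via QR. Reports
#' the coefficient covariance (residual variance times the inverse Gram
#' matrix), full-model r-squared and the compositional semi-partial
#' r-squared (full r-squared minus the covariate-only r-squared).
#'
#' @param y Numeric outcome vector.
#' @param ilr n x 2 matrix of ilr coordinates (columns `z1`, `z2`).
#' @param covariates n x p matrix or data frame of covariates (typically
#'   from [encode_covariates()]).
#' @param outcome Name carried in the fit (for reports).
#' @param basis The ilr basis used (metadata; needed by substitution
#'   prediction). Defaults to [ilr_basis()].
#' @return Object of class `ilr_fit`: list with `coefficients`, `vcov`,
#'   `sigma2`, `n`, `r2`, `r2_composition`, `p_values`, `outcome`, `basis`,
#'   `lm` (the underlying `stats::lm` fit).
#' @export
fit_ilr_regression <- function(y, ilr, covariates, outcome = "outcome",
                               basis = ilr_basis()) {
  ilr <- as.matrix(ilr)
  covariates <- as.matrix(covariates)
  if (ncol(ilr) != 2L) stop("ilr must have 2 columns")
  n <- length(y)
  if (nrow(ilr) != n || nrow(covariates) != n)
    stop("y, ilr and covariates must have matching rows")
  if (anyNA(y) || anyNA(ilr) || anyNA(covariates))
    stop("missing values are not allowed")
  p <- 1L + 2L + ncol(covariates)
  if (n <= p) stop("need more observations than parameters (n > ", p, ")")
  colnames(ilr) <- c("z1", "z2")
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  dat <- data.frame(y = y, ilr, covariates, check.names = TRUE)
  fit <- stats::lm(y ~ ., data = dat)
  if (fit$rank < p) {
    alias <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(alias, collapse = ", "))
  }
  sm <- summary(fit)
  fit0 <- stats::lm(y ~ ., data = dat[, setdiff(names(dat), c("z1", "z2")), drop = FALSE])
  structure(list(
    coefficients = stats::coef(fit),
    vcov = stats::vcov(fit),
    sigma2 = sm$sigma^2,
    n = n,
    r2 = sm$r.squared,
    r2_composition = sm$r.squared - summary(fit0)$r.squared,
    p_values = sm$coefficients[, "Pr(>|t|)"],
    outcome = outcome,
    basis = basis,
    lm = fit
  ), class = "ilr_fit")
}

#' @export
print.ilr_fit <- function(x, ...) {
  cat("ilr regression:", x$outcome, " (n =", x$n, ")\n")
  print(round(x$coefficients, 4))
  cat(sprintf("r2 = %.4f, compositional r2 = %.4f\n", x$r2, x$r2_composition))
  invisible(x)
}

#' Joint Wald test of the composition block
#'
#' Type-II test of the two ilr coefficients after all covariates:
#' `W = b' V^-1 b` for the (z1, z2) block, compared to chi-square with 2 df.
#' For this single compositional block the type-II (marginality) test
#' coincides with the joint Wald test after adjustment.
#'
#' @param fit An `ilr_fit`.
#' @return List `statistic`, `df`, `p_value`.
#' @export
composition_wald_test <- function(fit) {
  stopifnot(inherits(fit, "ilr_fit"))
  idx <- c("z1", "z2")
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx]
  if (!all(is.finite(V)) || abs(det(V)) < .Machine$double.xmin)
    stop("singular covariance block for (z1, z2)")
  stat <- drop(t(b) %*% solve(V, b))
  list(statistic = stat, df = 2L,
       p_value = stats::pchisq(stat, df = 2L, lower.tail = FALSE))
}

#' Naive single-behaviour regression
#'
#' Linear regression of the outcome on one behaviour's minutes plus
#' covariates, ignoring the compositional structure (the conventional
#' analysis the compositional model improves on). By default the outcome and
#' the behaviour are standardized to unit variance so the slope is a
#' standardized B with a 95% CI.
#'
#' @param y Outcome vector.
#' @param minutes Behaviour minutes vector.
#' @param covariates Covariate matrix / data frame.
#' @param standardize Standardize outcome and behaviour (default `TRUE`).
#' @param conf Confidence level (default 0.95).
#' @return List `B`, `ci`, `p_value`, `r2`, `standardized`.
#' @export
fit_single_behaviour_regression <- function(y, minutes, covariates,
                                            standardize = TRUE, conf = 0.95) {
  if (stats::sd(minutes) == 0) stop("behaviour has zero variance")
  if (standardize) {
    y <- as.numeric(scale(y))
    minutes <- as.numeric(scale(minutes))
  }
  dat <- data.frame(y = y, b = minutes, as.matrix(covariates), check.names = TRUE)
  fit <- stats::lm(y ~ ., data = dat)
  sm <- summary(fit)
  est <- stats::coef(fit)[["b"]]
  se <- sm$coefficients["b", "Std. Error"]
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = fit$df.residual)
  list(B = est, ci = c(est - tcrit * se, est + tcrit * se),
       p_value = sm$coefficients["b", "Pr(>|t|)"],
       r2 = sm$r.squared, standardized = standardize)
}

#' Regression diagnostics
#'
#' Advisory checks of the model assumptions: Shapiro-Wilk normality of
#' residuals, a Breusch-Pagan heteroscedasticity test, and studentized
#' residual outlier flags at |r| > 3. Nothing is dropped automatically.
#'
#' @param fit An `ilr_fit`.
#' @param outlier_threshold Studentized-residual flag threshold (default 3).
#' @return List `normality` (statistic, p or NA when n is out of range),
#'   `heteroscedasticity` (statistic, p), `outliers` (indices flagged),
#'   `n_flagged`.
#' @export
run_diagnostics <- function(fit, outlier_threshold = 3) {
  stopifnot(inherits(fit, "ilr_fit"))
  res <- stats::residuals(fit$lm)
  normality <- if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0) {
    sw <- stats::shapiro.test(res)
    list(statistic = unname(sw$statistic), p_value = sw$p.value)
  } else list(statistic = NA_real_, p_value = NA_real_)
  bp <- tryCatch(lmtest::bptest(fit$lm),
                 error = function(e) NULL)
  hetero <- if (is.null(bp)) list(statistic = NA_real_, p_value = NA_real_)
            else list(statistic = unname(bp$statistic), p_value = bp$p.value)
  rs <- tryCatch(stats::rstudent(fit$lm), error = function(e) rep(NA_real_, length(res)))
  # externally studentized residuals can overflow to NaN when the remaining
  # residual variance is ~0; the internal version is finite there
  bad <- !is.finite(rs)
  if (any(bad)) {
    ri <- tryCatch(stats::rstandard(fit$lm), error = function(e) rs)
    rs[bad] <- ri[bad]
  }
  flagged <- which(is.finite(rs) & abs(rs) > outlier_threshold)
  list(normality = normality, heteroscedasticity = hetero,
       outliers = flagged, n_flagged = length(flagged))
}

#' Predicted outcome difference for a time reallocation
#'
#' Isotemporal substitution through the fitted compositional model: the
#' baseline composition is perturbed by moving `delta` minutes from one
#' behaviour to another, both compositions are expressed in ilr coordinates,
#' and the coordinate difference is pushed through the compositional
#' coefficients. Covariates cancel, so
#' `estimate = t(dz) %*% b_comp`, `var = t(dz) %*% V_comp %*% dz`, with a
#' delta-method CI (normal 1.96 by default, or a t quantile).
#'
#' @param fit An `ilr_fit`.
#' @param baseline Length-3 baseline composition in minutes (typically the
#'   sample geometric-mean composition).
#' @param add,remove Behaviour names (see [behaviour_parts()]).
#' @param delta Minutes reallocated (default 5).
#' @param conf Confidence level (default 0.95).
#' @param critical `"normal"` (default) or `"t"` (df = n - p).
#' @param method `"exact"` errors on an infeasible reallocation; `"clamp"`
#'   floors the donor at the zero-replacement epsilon so the perturbed
#'   composition stays on the simplex.
#' @return One-row data frame of class `realloc_estimate`: `outcome`, `add`,
#'   `remove`, `delta`, `estimate`, `se`, `ci_low`, `ci_high`,
#'   `significant`.
#' @export
predict_reallocation_difference <- function(fit, baseline, add, remove,
                                            delta = 5, conf = 0.95,
                                            critical = c("normal", "t"),
                                            method = c("exact", "clamp")) {
  stopifnot(inherits(fit, "ilr_fit"))
  critical <- match.arg(critical)
  method <- match.arg(method)
  new_comp <- reallocate(baseline, add = add, remove = remove, delta = delta,
                         clamp = method == "clamp")
  idx <- c("z1", "z2")
  if (delta == 0) {
    dz <- c(0, 0)
  } else {
    dz <- ilr_transform(new_comp, basis = fit$basis) -
      ilr_transform(as_comp_matrix(baseline)[1L, ], basis = fit$basis)
  }
  b <- fit$coefficients[idx]
  V <- fit$vcov[idx, idx]
  est <- drop(dz %*% b)
  se <- sqrt(drop(t(dz) %*% V %*% dz))
  crit <- if (critical == "normal") stats::qnorm(1 - (1 - conf) / 2)
          else stats::qt(1 - (1 - conf) / 2, df = fit$lm$df.residual)
  lo <- est - crit * se
  hi <- est + crit * se
  out <- data.frame(outcome = fit$outcome, add = add, remove = remove,
                    delta = delta, estimate = est, se = se,
                    ci_low = lo, ci_high = hi,
                    significant = lo > 0 | hi < 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("realloc_estimate", "data.frame")
  out
}

#' Full isotemporal-substitution table
#'
#' All six ordered (add, remove) behaviour pairs for each fitted outcome,
#' with estimates, CIs and a significance flag (CI excludes zero). Cells
#' whose reallocation is infeasible under the exact raw-minutes route are
#' reported as NA with the error message, leaving other cells intact; no
#' multiple-testing correction is applied across cells.
#'
#' @param fits A single `ilr_fit` or a (named) list of them.
#' @param baseline Length-3 baseline composition in minutes.
#' @param delta Minutes reallocated (default 5).
#' @param conf,critical,method Passed to
#'   [predict_reallocation_difference()].
#' @return Data frame with one row per outcome x ordered pair; column
#'   `note` carries any per-cell feasibility error.
#' @export
isotemporal_table <- function(fits, baseline, delta = 5, conf = 0.95,
                              critical = "normal", method = "exact") {
  if (inherits(fits, "ilr_fit")) fits <- list(fits)
  parts <- behaviour_parts()
  pairs <- expand.grid(add = parts, remove = parts, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$add != pairs$remove, , drop = FALSE]
  rows <- list()
  for (fit in fits) {
    for (k in seq_len(nrow(pairs))) {
      cell <- tryCatch(
        cbind(predict_reallocation_difference(
          fit, baseline, add = pairs$add[k], remove = pairs$remove[k],
          delta = delta, conf = conf, critical = critical, method = method),
          note = ""),
        error = function(e) data.frame(
          outcome = fit$outcome, add = pairs$add[k], remove = pairs$remove[k],
          delta = delta, estimate = NA_real_, se = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, significant = NA,
          note = conditionMessage(e), stringsAsFactors = FALSE)
      )
      rows[[length(rows) + 1L]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
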