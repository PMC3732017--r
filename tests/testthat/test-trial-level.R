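# Trial-level weighted regression, prediction intervals and the
# surrogate threshold effect, checked against lm()/predict.lm() oracles
# and grid searches.

test_that("collinear trial effects give R^2 = 1 and zero residual variance", {
  s <- tibble::tibble(
    trial_id = 1:4, n_patients = c(50, 400, 120, 90),
    log_hr_surrogate = c(-0.4, -0.1, 0.2, 0.5),
    log_hr_true = 0.3 + 0.7 * c(-0.4, -0.1, 0.2, 0.5)
  )
  fit <- fit_trial_regression(s, n_boot = 0)
  expect_equal(fit$r_squared, 1)
  expect_lt(fit$sigma2, 1e-20)
  expect_equal(unname(fit$coefficients), c(0.3, 0.7), tolerance = 1e-10)
  # prediction interval collapses to the fitted line
  pi <- prediction_interval(fit, 0.1)
  expect_equal(pi$lwr, pi$upr, tolerance = 1e-10)
  expect_equal(pi$fit, 0.3 + 0.07, tolerance = 1e-10)
})

test_that("WLS coefficients and R^2 match the lm() normal-equation oracle", {
  # the spec'd 3-point fixture
  s3 <- tibble::tibble(
    trial_id = 1:3, n_patients = c(100, 200, 100),
    log_hr_surrogate = c(-0.2, 0, 0.4), log_hr_true = c(-0.1, 0, 0.1)
  )
  fit <- fit_trial_regression(s3, n_boot = 0)
  oracle <- oracle_wls(s3$log_hr_surrogate, s3$log_hr_true, s3$n_patients)
  expect_equal(unname(fit$coefficients), oracle$coef, tolerance = 1e-10)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)

  s6 <- trial_summary_fixture()
  for (intercept in c(TRUE, FALSE)) {
    fit <- fit_trial_regression(s6, intercept = intercept, n_boot = 0)
    oracle <- oracle_wls(s6$log_hr_surrogate, s6$log_hr_true,
      s6$n_patients,
      intercept = intercept
    )
    got <- unname(fit$coefficients)
    if (!intercept) got <- got[2]
    expect_equal(got, oracle$coef, tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
    expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-10)
  }
})

test_that("results are invariant to rescaling all weights", {
  s <- trial_summary_fixture()
  f1 <- fit_trial_regression(s, n_boot = 0)
  s2 <- dplyr::mutate(s, n_patients = n_patients * 37)
  f2 <- fit_trial_regression(s2, n_boot = 0)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-12)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
  expect_equal(f2$sigma2, f1$sigma2, tolerance = 1e-12)
  expect_equal(
    prediction_interval(f2, -0.2), prediction_interval(f1, -0.2),
    tolerance = 1e-12
  )
})

test_that("noise with no surrogate signal gives R^2 near zero, degenerate inputs reject", {
  set.seed(14)
  s <- tibble::tibble(
    trial_id = 1:25, n_patients = 200,
    log_hr_surrogate = stats::rnorm(25, 0, 0.3),
    log_hr_true = stats::rnorm(25, 0, 0.3)
  )
  fit <- fit_trial_regression(s, n_boot = 0)
  expect_lt(fit$r_squared, 0.2)

  expect_error(fit_trial_regression(s[1:2, ], n_boot = 0), "At least 3")
  flat <- dplyr::mutate(s, log_hr_surrogate = 0.1)
  expect_error(fit_trial_regression(flat, n_boot = 0), "Zero variance")
})

test_that("prediction intervals match predict.lm and are narrowest at the weighted mean", {
  s <- trial_summary_fixture()
  fit <- fit_trial_regression(s, n_boot = 0)
  for (x0 in c(-0.5, -0.2, 0, 0.3)) {
    got <- prediction_interval(fit, x0)
    want <- oracle_prediction_interval(
      s$log_hr_surrogate, s$log_hr_true, s$n_patients,
      x0,
      w0_raw = fit$weighted_mean_size
    )
    expect_equal(c(got$fit, got$lwr, got$upr), want, tolerance = 1e-10)
  }
  # leverage is minimised at the weighted mean surrogate effect
  wmean <- with(s, sum(n_patients * log_hr_surrogate) / sum(n_patients))
  grid <- seq(-0.6, 0.4, length.out = 101)
  widths <- with(prediction_interval(fit, c(grid, wmean)), upr - lwr)
  expect_equal(which.min(widths), 102L)
  expect_error(prediction_interval(fit, 0, level = 1.2), "between 0 and 1")
})

test_that("surrogate threshold effect: degenerate limit, monotonicity, grid oracle", {
  # zero residual variance, identity line: any surrogate benefit predicts
  # an OS benefit
  s_exact <- tibble::tibble(
    trial_id = 1:4, n_patients = 100,
    log_hr_surrogate = c(-0.4, -0.2, 0.1, 0.3),
    log_hr_true = c(-0.4, -0.2, 0.1, 0.3)
  )
  fit <- fit_trial_regression(s_exact, n_boot = 0)
  expect_equal(surrogate_threshold_effect(fit)$ste_hr, 1, tolerance = 1e-6)

  # STE moves away from 1 as residual variance grows
  make_noisy <- function(sd_resid, seed = 33) {
    withr::with_seed(seed, tibble::tibble(
      trial_id = 1:12, n_patients = 150,
      log_hr_surrogate = seq(-0.5, 0.3, length.out = 12),
      log_hr_true = seq(-0.5, 0.3, length.out = 12) +
        stats::rnorm(12, 0, sd_resid)
    ))
  }
  ste <- vapply(c(0.02, 0.05, 0.1), function(sd) {
    surrogate_threshold_effect(
      fit_trial_regression(make_noisy(sd), n_boot = 0)
    )$ste_hr
  }, 1)
  expect_true(all(diff(ste) < 0))

  # grid-search oracle on the upper prediction limit
  fit <- fit_trial_regression(trial_summary_fixture(), n_boot = 0)
  got <- surrogate_threshold_effect(fit)$ste_hr
  hr_grid <- seq(0.2, 1.5, by = 1e-4)
  upr <- prediction_interval(fit, log(hr_grid))$upr
  grid_ste <- hr_grid[max(which(upr <= 0))]
  expect_lt(abs(got - grid_ste), 1e-3)

  # inverted effect direction is reported, not computed
  inv <- dplyr::mutate(trial_summary_fixture(),
    log_hr_true = -log_hr_true
  )
  res <- surrogate_threshold_effect(fit_trial_regression(inv, n_boot = 0))
  expect_true(is.na(res$ste_hr))
  expect_match(res$reason, "inverted")
})

test_that("R^2 bootstrap interval brackets the estimate", {
  s <- trial_summary_fixture()
  fit <- withr::with_seed(2, fit_trial_regression(s, n_boot = 200))
  expect_lte(fit$ci_low, fit$r_squared)
  expect_gte(fit$ci_high, fit$r_squared)
  expect_true(fit$ci_low >= 0 && fit$ci_high <= 1)
})
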