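# Leave-one-trial-out validation and the fixed-horizon sensitivity
# analysis.

test_that("exchangeable trials with a common true effect are all inside", {
  s <- tibble::tibble(
    trial_id = 1:6, n_patients = 150,
    log_hr_surrogate = seq(-0.5, 0.2, length.out = 6),
    log_hr_true = -0.25
  )
  loo <- loo_validate(s)
  expect_equal(loo$predicted_log_hr_true, rep(-0.25, 6), tolerance = 1e-10)
  expect_true(all(loo$inside))
  expect_identical(attr(loo, "n_inside"), 6L)
})

test_that("a gross outlier among collinear trials is the only one flagged outside", {
  s <- tibble::tibble(
    trial_id = 1:11, n_patients = 120,
    log_hr_surrogate = seq(-0.5, 0.5, length.out = 11),
    log_hr_true = 0.9 * seq(-0.5, 0.5, length.out = 11)
  )
  s$log_hr_true[4] <- s$log_hr_true[4] + 1
  loo <- loo_validate(s)
  expect_false(loo$inside[4])
  expect_true(all(loo$inside[-4]))
})

test_that("LOO predictions ignore the left-out trial's own OS summary", {
  s <- trial_summary_fixture()
  loo <- loo_validate(s)
  bumped <- s
  bumped$log_hr_true[2] <- bumped$log_hr_true[2] + 5
  loo_b <- loo_validate(bumped)
  expect_equal(loo_b$predicted_log_hr_true[2], loo$predicted_log_hr_true[2],
    tolerance = 1e-12
  )
  expect_equal(loo_b$pi_low[2], loo$pi_low[2], tolerance = 1e-12)
  expect_false(loo_b$inside[2])
})

test_that("containment count is invariant to trial ordering", {
  s <- trial_summary_fixture()
  shuffled <- s[c(4, 1, 6, 2, 5, 3), ]
  expect_identical(
    attr(loo_validate(s), "n_inside"),
    attr(loo_validate(shuffled), "n_inside")
  )
  expect_error(loo_validate(s[1:3, ]), "at least 4")
})

test_that("both left-out-weight conventions work and differ only in width", {
  s <- trial_summary_fixture()
  own <- loo_validate(s, weight_convention = "own")
  mean_w <- loo_validate(s, weight_convention = "mean")
  expect_equal(own$predicted_log_hr_true, mean_w$predicted_log_hr_true,
    tolerance = 1e-12
  )
  expect_false(identical(own$pi_low, mean_w$pi_low))
})

test_that("infinite horizons reproduce the unrestricted analysis bit-identically", {
  cfg <- simulation_config(
    n_trials = 6, patients_per_trial = 150,
    excess_hazard = 0.4, seed = 37
  )
  obs <- derive_endpoints(simulate_event_history(cfg), c("dfs", "os"))
  unrestricted <- fit_trial_regression(trial_summaries(obs, "dfs"), n_boot = 0)
  horizon <- sensitivity_fixed_horizon(obs,
    surrogate_horizon = Inf,
    os_horizon = Inf, n_boot = 0
  )
  expect_identical(horizon$coefficients, unrestricted$coefficients)
  expect_identical(horizon$sigma2, unrestricted$sigma2)
  expect_identical(horizon$r_squared, unrestricted$r_squared)
})

test_that("an early-information horizon preserves the trial-level association", {
  cfg <- simulation_config(
    n_trials = 12, patients_per_trial = 500,
    copula_tau = 0.5, baseline_hazard_surrogate = 0.55,
    baseline_hazard_true = 0.3, excess_hazard = 0.6,
    trial_effect_correlation = 0.95,
    trial_effect_sd_surrogate = 0.3, trial_effect_sd_true = 0.3,
    censoring_rate = 0.02, admin_horizon = 10, seed = 41
  )
  obs <- derive_endpoints(simulate_event_history(cfg), c("dfs", "os"))
  dfs <- obs[obs$endpoint_name == "dfs", ]
  frac_early <- sum(dfs$event & dfs$time <= 3) / sum(dfs$event)
  expect_gte(frac_early, 0.8) # the study condition the check relies on
  unrestricted <- fit_trial_regression(trial_summaries(obs, "dfs"), n_boot = 0)
  horizon <- sensitivity_fixed_horizon(obs,
    surrogate_horizon = 3,
    os_horizon = 5, n_boot = 0
  )
  expect_lt(abs(horizon$r_squared - unrestricted$r_squared), 0.1)
})

test_that("degenerate and inverted horizons are rejected or warned about", {
  cfg <- simulation_config(n_trials = 4, patients_per_trial = 120, seed = 43)
  obs <- derive_endpoints(simulate_event_history(cfg), c("dfs", "os"))
  expect_error(
    suppressWarnings(
      sensitivity_fixed_horizon(obs, surrogate_horizon = 1e-9,
        os_horizon = 5, n_boot = 0)
    ),
    "No surrogate events"
  )
  expect_warning(
    sensitivity_fixed_horizon(obs, surrogate_horizon = 6, os_horizon = 4,
      n_boot = 0),
    "earlier"
  )
})
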