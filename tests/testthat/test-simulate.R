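# Synthetic-data generator: determinism, substreams, invariants,
# recovery of the configured association structure.

test_that("configuration rejects invalid parameters with clear messages", {
  expect_error(
    simulation_config(baseline_hazard_true = 0),
    "hazard.*positive"
  )
  expect_error(simulation_config(copula_tau = 1), "\\[0, 1\\)")
  expect_error(
    simulation_config(copula_family = "independence", copula_tau = 0.3),
    "must be 0"
  )
  expect_error(
    simulation_config(trial_effect_correlation = 1.2),
    "\\[-1, 1\\]"
  )
  expect_error(simulation_config(admin_horizon = 0), "> 0")
  expect_error(simulation_config(censoring_rate = -1), ">= 0")
})

test_that("simulation is deterministic and trial substreams are stable", {
  cfg <- simulation_config(n_trials = 3, patients_per_trial = 40, seed = 17)
  expect_identical(simulate_meta_analysis(cfg), simulate_meta_analysis(cfg))
  expect_identical(simulate_event_history(cfg), simulate_event_history(cfg))

  # adding trials never reshuffles earlier trials
  cfg5 <- simulation_config(n_trials = 5, patients_per_trial = 40, seed = 17)
  strip <- function(d) {
    attr(d, "trial_effects") <- NULL
    attr(d, "latents") <- NULL
    d
  }
  r3 <- simulate_meta_analysis(cfg)
  r5 <- simulate_meta_analysis(cfg5)
  expect_identical(strip(r3), strip(r5[r5$trial_id <= 3, ]))
})

test_that("records satisfy the subject-record invariants", {
  cfg <- simulation_config(
    n_trials = 4, patients_per_trial = 200,
    excess_hazard = 0.6, censoring_rate = 0.1, seed = 23
  )
  for (rec in list(simulate_meta_analysis(cfg), simulate_event_history(cfg))) {
    expect_silent(surroval:::validate_records(rec))
    for (ev in c("locoregional", "distant", "death")) {
      tm <- rec[[paste0("time_", ev)]]
      fl <- rec[[paste0("event_", ev)]]
      expect_identical(fl, !is.na(tm))
      expect_true(all(tm[fl] <= rec$time_last_followup[fl]))
      expect_true(all(tm >= 0, na.rm = TRUE))
    }
  }
})

test_that("no censoring and a long horizon give death events for everyone", {
  cfg <- simulation_config(
    n_trials = 2, patients_per_trial = 500,
    censoring_rate = 0, admin_horizon = 1e4, seed = 3
  )
  expect_true(all(simulate_meta_analysis(cfg)$event_death))
  expect_true(all(simulate_event_history(cfg)$event_death))
})

test_that("a vanishing administrative horizon censors every record", {
  cfg <- simulation_config(
    n_trials = 2, patients_per_trial = 200,
    censoring_rate = 0, admin_horizon = 1e-9, seed = 3
  )
  rec <- simulate_meta_analysis(cfg)
  expect_false(any(rec$event_death | rec$event_distant))
  expect_true(all(rec$time_last_followup == 1e-9))
})

test_that("uncensored margins recover the configured Kendall tau", {
  pairs0 <- simulate_margin_pairs(10000, 0, "independence", seed = 31)
  expect_equal(
    cor(pairs0$surrogate_time, pairs0$os_time, method = "kendall"),
    0,
    tolerance = 0.03
  )
  pairs5 <- simulate_margin_pairs(10000, 0.5, "clayton", seed = 31)
  expect_equal(
    cor(pairs5$surrogate_time, pairs5$os_time, method = "kendall"),
    0.5,
    tolerance = 0.03
  )
})

test_that("large-n per-trial Cox estimates recover the drawn trial effects", {
  cfg <- simulation_config(
    n_trials = 2, patients_per_trial = 20000,
    copula_tau = 0.4, censoring_rate = 0, admin_horizon = 1e4,
    trial_effect_sd_surrogate = 0.3, trial_effect_sd_true = 0.3, seed = 47
  )
  rec <- simulate_meta_analysis(cfg)
  drawn <- attr(rec, "trial_effects")
  obs <- derive_endpoints(rec, c("distant", "os"))
  est <- trial_summaries(obs, surrogate = "distant")
  expect_lt(max(abs(est$log_hr_surrogate - drawn$log_hr_surrogate)), 0.05)
  expect_lt(max(abs(est$log_hr_true - drawn$log_hr_true)), 0.05)
})

test_that("no between-trial signal on survival gives a flat trial-level slope", {
  cfg <- simulation_config(
    n_trials = 10, patients_per_trial = 2000,
    trial_effect_sd_surrogate = 0.3, trial_effect_sd_true = 0,
    trial_effect_correlation = 0, censoring_rate = 0, admin_horizon = 100,
    seed = 7
  )
  obs <- derive_endpoints(simulate_meta_analysis(cfg), c("distant", "os"))
  fit <- fit_trial_regression(trial_summaries(obs, surrogate = "distant"),
    n_boot = 0
  )
  expect_lt(abs(fit$coefficients["slope"]), 0.15)
})

test_that("event-history generator recovers the latent progression-death association", {
  # excess hazard 0: death depends on progression only through the copula
  cfg_ind <- simulation_config(
    n_trials = 1, patients_per_trial = 8000,
    copula_family = "independence", copula_tau = 0,
    excess_hazard = 0, censoring_rate = 0, admin_horizon = 1e4, seed = 13
  )
  lat <- attr(simulate_event_history(cfg_ind), "latents")
  expect_equal(
    cor(lat$latent_progression, lat$latent_death, method = "kendall"), 0,
    tolerance = 0.03
  )

  cfg_dep <- simulation_config(
    n_trials = 1, patients_per_trial = 8000,
    copula_tau = 0.5, excess_hazard = 0, censoring_rate = 0,
    admin_horizon = 1e4, seed = 13
  )
  lat <- attr(simulate_event_history(cfg_dep), "latents")
  expect_equal(
    cor(lat$latent_progression, lat$latent_death, method = "kendall"), 0.5,
    tolerance = 0.03
  )
})
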