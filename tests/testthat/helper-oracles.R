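# Independent reference implementations used as oracles. These are kept
# deliberately naive (scalar loops, explicit formulas) and share no code
# with the package internals they check.

# Efron-corrected Cox partial log-likelihood for a single binary
# covariate, written out term by term.
efron_partial_loglik <- function(beta, time, event, arm) {
  ll <- 0
  for (t in sort(unique(time[event]))) {
    tied <- which(event & time == t)
    risk <- which(time >= t)
    d <- length(tied)
    sum_risk <- sum(exp(beta * arm[risk]))
    sum_tied <- sum(exp(beta * arm[tied]))
    ll <- ll + beta * sum(arm[tied])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_risk - (l / d) * sum_tied)
    }
  }
  ll
}

oracle_cox_log_hr <- function(time, event, arm) {
  stats::optimize(function(b) efron_partial_loglik(b, time, event, arm),
    interval = c(-8, 8), maximum = TRUE, tol = 1e-12
  )$maximum
}

# Product-limit estimator computed by hand, one distinct time at a time.
oracle_km <- function(time, event) {
  s <- 1
  out <- data.frame(time = numeric(), survival = numeric())
  for (t in sort(unique(time))) {
    at_risk <- sum(time >= t)
    d <- sum(event & time == t)
    if (d > 0) s <- s * (1 - d / at_risk)
    out <- rbind(out, data.frame(time = t, survival = s))
  }
  out
}

# Weighted least squares via lm() on mean-normalised weights: the
# independent route to the same normal equations wls_core solves by hand.
oracle_wls <- function(x, y, w, intercept = TRUE) {
  w <- w / mean(w)
  fit <- if (intercept) {
    stats::lm(y ~ x, weights = w)
  } else {
    stats::lm(y ~ x - 1, weights = w)
  }
  list(
    coef = unname(stats::coef(fit)),
    r_squared = summary(fit)$r.squared,
    sigma2 = summary(fit)$sigma^2
  )
}

# Prediction interval via predict.lm on mean-normalised weights.
oracle_prediction_interval <- function(x, y, raw_w, x0, w0_raw, level = 0.95) {
  w <- raw_w / mean(raw_w)
  fit <- stats::lm(y ~ x, weights = w)
  as.numeric(stats::predict(fit,
    newdata = data.frame(x = x0),
    interval = "prediction", level = level,
    weights = w0_raw / mean(raw_w)
  ))
}

# Scalar brute-force endpoint derivations over one record.
ref_os <- function(r) {
  if (isTRUE(r$event_death)) {
    list(time = r$time_death, event = TRUE)
  } else {
    list(time = r$time_last_followup, event = FALSE)
  }
}

ref_dfs <- function(r) {
  times <- c(
    if (isTRUE(r$event_locoregional)) r$time_locoregional,
    if (isTRUE(r$event_distant)) r$time_distant,
    if (isTRUE(r$event_death)) r$time_death
  )
  if (length(times) > 0) {
    list(time = min(times), event = TRUE)
  } else {
    list(time = r$time_last_followup, event = FALSE)
  }
}

ref_lrc <- function(r) {
  comp <- min(c(
    if (isTRUE(r$event_distant)) r$time_distant,
    if (isTRUE(r$event_death)) r$time_death,
    r$time_last_followup
  ))
  if (isTRUE(r$event_locoregional) && r$time_locoregional <= comp) {
    list(time = r$time_locoregional, event = TRUE)
  } else {
    list(time = comp, event = FALSE)
  }
}

# One-record tibble in the subject-record layout.
make_record <- function(loco = NA, distant = NA, death = NA, fu = 10) {
  tibble::tibble(
    trial_id = 1L, patient_id = "p1", arm = 0L,
    time_locoregional = as.numeric(loco),
    event_locoregional = !is.na(loco),
    time_distant = as.numeric(distant),
    event_distant = !is.na(distant),
    time_death = as.numeric(death),
    event_death = !is.na(death),
    time_last_followup = as.numeric(fu)
  )
}

# Simulated pairs on the raw copula margins (surrogate margin recorded as
# the distant event), for individual-level estimator checks.
simulate_margin_pairs <- function(n, tau, family = "clayton",
                                  censoring_rate = 0, admin_horizon = 1000,
                                  seed = 1) {
  cfg <- simulation_config(
    n_trials = 1, patients_per_trial = n,
    copula_family = family, copula_tau = tau,
    censoring_rate = censoring_rate, admin_horizon = admin_horizon,
    seed = seed
  )
  obs <- derive_endpoints(simulate_meta_analysis(cfg), c("distant", "os"))
  surrogacy_pairs(obs, "distant")
}

# 20-subject fixture with tied event times for the Cox oracle check.
cox_fixture <- function() {
  tibble::tibble(
    time = c(
      1, 1, 2, 2, 3, 4, 4, 5, 6, 7,
      1, 2, 2, 3, 3, 5, 5, 6, 7, 8
    ),
    event = c(
      TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
      TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE
    ),
    arm = rep(0:1, each = 10)
  )
}

trial_summary_fixture <- function() {
  tibble::tibble(
    trial_id = 1:6,
    n_patients = c(120, 340, 210, 95, 410, 180),
    log_hr_surrogate = c(-0.45, -0.30, -0.10, 0.05, -0.25, 0.15),
    log_hr_true = c(-0.38, -0.22, -0.12, 0.10, -0.18, 0.08),
    se_surrogate = rep(0.1, 6),
    se_true = rep(0.1, 6)
  )
}
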