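# Verbal classification of squared correlations and assembly of the full
# per-comparison surrogacy report.

#' Classify a squared correlation coefficient
#'
#' Verbal scale for individual-level rho^2 and trial-level R^2: values
#' higher than 0.9 are "excellent", higher than 0.75 "very good", higher
#' than 0.5 "good", higher than 0.25 "moderate", and values of 0.25 or
#' lower "poor". Bins are half-open: a value must be strictly higher than
#' a boundary to take the stronger label (0.75 is "good", 0.25 is
#' "poor").
#'
#' @param value Squared correlation(s) in `[0, 1]`.
#' @return A character vector of labels.
#' @examples
#' classify_correlation(c(0.92, 0.75, 0.25))
#' @export
classify_correlation <- function(value) {
  if (any(!is.finite(value) | value < 0 | value > 1)) {
    rlang::abort("Squared correlations must lie in [0, 1].")
  }
  labels <- c("poor", "moderate", "good", "very good", "excellent")
  labels[findInterval(value, c(0.25, 0.5, 0.75, 0.9), left.open = TRUE) + 1]
}

#' Run the full surrogacy analysis for one comparison
#'
#' Chains endpoint derivation, per-trial Cox summaries, the
#' individual-level copula model, the trial-level weighted regression
#' with surrogate threshold effect, leave-one-trial-out validation and
#' the fixed-horizon sensitivity analysis, and assembles a single report.
#'
#' @param records A subject-record tibble ([simulate_event_history()], or
#'   real data in the same layout).
#' @param surrogate Surrogate endpoint: `"dfs"`, `"pfs"` or
#'   `"locoregional_control"`.
#' @param comparison Free-text label of the treatment comparison.
#' @param family Copula family for the individual level.
#' @param surrogate_horizon,os_horizon Horizons (years) of the
#'   fixed-horizon sensitivity analysis.
#' @param n_boot_individual,n_boot_trial Bootstrap replicates for the
#'   rho^2 and R^2 confidence intervals.
#' @param seed Optional seed fixing the bootstrap resampling (the point
#'   estimates are deterministic regardless).
#' @return An object of class `"surrogacy_report"`; see [tidy()] /
#'   [glance()] methods and `print()`.
#' @examples
#' cfg <- simulation_config(n_trials = 5, patients_per_trial = 120, seed = 2)
#' rep <- build_report(simulate_event_history(cfg),
#'   surrogate = "dfs",
#'   n_boot_individual = 0, n_boot_trial = 50, seed = 1
#' )
#' @export
build_report <- function(records,
                         surrogate = c("dfs", "pfs", "locoregional_control"),
                         comparison = "experimental vs control",
                         family = c("clayton", "gumbel", "independence"),
                         surrogate_horizon = 3,
                         os_horizon = 5,
                         n_boot_individual = 200,
                         n_boot_trial = 2000,
                         seed = NULL) {
  surrogate <- rlang::arg_match(surrogate)
  family <- rlang::arg_match(family)
  validate_records(records)
  n_trials <- length(unique(records$trial_id))
  if (n_trials < 3) {
    rlang::abort(sprintf(
      "A surrogacy comparison needs at least 3 trials; got %d. Pool more trials or skip the trial-level analysis.",
      n_trials
    ))
  }
  run <- function(expr) {
    if (is.null(seed)) expr else withr::with_seed(seed, expr)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  observations <- stage(
    "endpoints",
    derive_endpoints(records, c(surrogate, "os"))
  )
  individual <- stage("individual_level", run(
    fit_copula(surrogacy_pairs(observations, surrogate),
      family = family, n_boot = n_boot_individual
    )
  ))
  summaries <- stage("survival_core", trial_summaries(observations, surrogate))
  trial <- stage("trial_level", run(
    fit_trial_regression(summaries, n_boot = n_boot_trial)
  ))
  ste <- stage("trial_level", surrogate_threshold_effect(trial))
  loo <- stage("validation", loo_validate(summaries))
  horizon <- stage("validation", run(
    sensitivity_fixed_horizon(observations,
      surrogate = surrogate,
      surrogate_horizon = surrogate_horizon, os_horizon = os_horizon,
      n_boot = n_boot_trial
    )
  ))

  structure(
    list(
      comparison = comparison,
      surrogate = surrogate,
      true = "os",
      n_trials = nrow(summaries),
      n_patients = length(unique(records$patient_id)),
      individual = individual,
      trial = trial,
      ste = ste,
      loo = loo,
      horizon = horizon,
      horizons = c(surrogate = surrogate_horizon, os = os_horizon),
      labels = c(
        individual = classify_correlation(individual$rho_squared),
        trial = classify_correlation(trial$r_squared)
      )
    ),
    class = "surrogacy_report"
  )
}

#' @export
print.surrogacy_report <- function(x, ...) {
  cat(sprintf(
    "Surrogacy report: %s (%s vs overall survival)\n",
    x$comparison, toupper(x$surrogate)
  ))
  cat(sprintf("  %d patients in %d trials\n\n", x$n_patients, x$n_trials))
  print(x$individual)
  cat("\n")
  print(x$trial)
  ste_txt <- if (is.na(x$ste$ste_hr)) {
    paste0("undefined (", x$ste$reason, ")")
  } else {
    sprintf("%.2f", x$ste$ste_hr)
  }
  cat(sprintf("  surrogate threshold effect (HR): %s\n\n", ste_txt))
  cat(sprintf(
    "Leave-one-trial-out: inside the prediction interval in %d of %d trials\n",
    attr(x$loo, "n_inside"), attr(x$loo, "n_trials")
  ))
  cat(sprintf(
    "Fixed-horizon sensitivity (%g-year %s vs %g-year OS): R^2 = %.3f [%s]\n",
    x$horizons["surrogate"], toupper(x$surrogate), x$horizons["os"],
    x$horizon$r_squared, classify_correlation(x$horizon$r_squared)
  ))
  invisible(x)
}

#' @method tidy surrogacy_report
#' @export
tidy.surrogacy_report <- function(x, ...) {
  tibble::tibble(
    comparison = x$comparison,
    surrogate = x$surrogate,
    n_patients = x$n_patients,
    n_trials = x$n_trials,
    rho_squared = x$individual$rho_squared,
    rho2_ci_low = x$individual$ci_low,
    rho2_ci_high = x$individual$ci_high,
    rho2_label = unname(x$labels["individual"]),
    r_squared = x$trial$r_squared,
    r2_ci_low = x$trial$ci_low,
    r2_ci_high = x$trial$ci_high,
    r2_label = unname(x$labels["trial"]),
    horizon_r_squared = x$horizon$r_squared,
    ste_hr = x$ste$ste_hr,
    loo_inside = attr(x$loo, "n_inside"),
    loo_trials = attr(x$loo, "n_trials")
  )
}

#' Serialise a surrogacy report to JSON
#'
#' Full-precision serialisation of every reported number (display
#' rounding is left to the caller, so confidence intervals never collapse
#' by rounding). The result re-parses losslessly with
#' [jsonlite::fromJSON()].
#'
#' @param x A [build_report()] object.
#' @return A JSON string.
#' @export
report_json <- function(x) {
  stopifnot(inherits(x, "surrogacy_report"))
  payload <- list(
    comparison = x$comparison,
    surrogate = x$surrogate,
    n_patients = x$n_patients,
    n_trials = x$n_trials,
    individual = x$individual[c(
      "family", "theta", "kendall_tau", "spearman_rho", "rho_squared",
      "ci_low", "ci_high", "n_pairs"
    )],
    individual_label = unname(x$labels["individual"]),
    trial = list(
      intercept = unname(x$trial$coefficients["intercept"]),
      slope = unname(x$trial$coefficients["slope"]),
      sigma2 = x$trial$sigma2,
      r_squared = x$trial$r_squared,
      ci_low = x$trial$ci_low,
      ci_high = x$trial$ci_high,
      n_trials = x$trial$n_trials
    ),
    trial_label = unname(x$labels["trial"]),
    ste_hr = x$ste$ste_hr,
    loo = list(
      n_inside = attr(x$loo, "n_inside"),
      n_trials = attr(x$loo, "n_trials"),
      trials = tibble::as_tibble(x$loo)
    ),
    horizon = list(
      surrogate_horizon = unname(x$horizons["surrogate"]),
      os_horizon = unname(x$horizons["os"]),
      r_squared = x$horizon$r_squared
    )
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
}
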