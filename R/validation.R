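# Leave-one-trial-out cross-validation of the trial-level model, and the
# fixed-horizon sensitivity analysis.

#' Leave-one-trial-out validation of the surrogacy model
#'
#' Each trial is left out once; the weighted regression is rebuilt on the
#' remaining trials and applied to the left-out trial's surrogate effect,
#' with a 95% prediction interval. By default the prediction interval
#' uses the left-out trial's own size as weight (its size is known when
#' predicting for it); `weight_convention = "mean"` uses the refit's
#' weighted mean trial size instead.
#'
#' @inheritParams fit_trial_regression
#' @param level Prediction level.
#' @param weight_convention `"own"` (default) or `"mean"`.
#' @return A tibble of class `"surrogacy_loo"` with one row per trial:
#'   `trial_id`, `observed_log_hr_true`, `predicted_log_hr_true`,
#'   `pi_low`, `pi_high`, `inside`; attributes `n_inside` and `n_trials`.
#' @examples
#' s <- tibble::tibble(
#'   trial_id = 1:5, n_patients = c(100, 150, 200, 120, 180),
#'   log_hr_surrogate = c(-0.4, -0.2, 0, 0.1, 0.3),
#'   log_hr_true = c(-0.33, -0.18, 0.02, 0.05, 0.28)
#' )
#' loo_validate(s)
#' @export
loo_validate <- function(summaries,
                         weight_by = c("patients", "events"),
                         intercept = TRUE,
                         level = 0.95,
                         weight_convention = c("own", "mean")) {
  weight_by <- rlang::arg_match(weight_by)
  weight_convention <- rlang::arg_match(weight_convention)
  k <- nrow(summaries)
  if (k < 4) {
    rlang::abort(sprintf(
      "Leave-one-trial-out needs at least 4 trials (each refit needs 3; got %d).",
      k
    ))
  }
  rows <- purrr::map(seq_len(k), function(i) {
    refit <- tryCatch(
      fit_trial_regression(summaries[-i, ],
        weight_by = weight_by,
        intercept = intercept, n_boot = 0
      ),
      error = function(e) {
        rlang::abort(sprintf(
          "Refit without trial '%s' failed: %s",
          summaries$trial_id[i], conditionMessage(e)
        ))
      }
    )
    w <- if (weight_convention == "own") {
      if (weight_by == "patients") {
        summaries$n_patients[i]
      } else {
        summaries$n_events[i]
      }
    } else {
      NULL
    }
    pi <- prediction_interval(refit, summaries$log_hr_surrogate[i],
      level = level, weight = w
    )
    obs <- summaries$log_hr_true[i]
    tibble::tibble(
      trial_id = summaries$trial_id[i],
      observed_log_hr_true = obs,
      predicted_log_hr_true = pi$fit,
      pi_low = pi$lwr,
      pi_high = pi$upr,
      inside = pi$lwr <= obs & obs <= pi$upr
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
    class = c("surrogacy_loo", class(out)),
    n_inside = sum(out$inside),
    n_trials = k,
    level = level,
    weight_convention = weight_convention
  )
}

#' @export
print.surrogacy_loo <- function(x, ...) {
  cat(sprintf(
    "Leave-one-trial-out validation: observed OS effect inside the %.0f%% prediction interval in %d of %d trials\n",
    100 * attr(x, "level"), attr(x, "n_inside"), attr(x, "n_trials")
  ))
  NextMethod()
}

#' @method glance surrogacy_loo
#' @export
glance.surrogacy_loo <- function(x, ...) {
  tibble::tibble(
    n_trials = attr(x, "n_trials"),
    n_inside = attr(x, "n_inside"),
    containment = attr(x, "n_inside") / attr(x, "n_trials"),
    level = attr(x, "level")
  )
}

#' @method autoplot surrogacy_loo
#' @export
autoplot.surrogacy_loo <- function(object, ...) {
  d <- dplyr::mutate(tibble::as_tibble(object),
    trial = factor(.data$trial_id, levels = rev(unique(.data$trial_id)))
  )
  ggplot2::ggplot(d, ggplot2::aes(y = .data$trial)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = exp(.data$pi_low), xmax = exp(.data$pi_high)),
      height = 0.25
    ) +
    ggplot2::geom_point(ggplot2::aes(x = exp(.data$predicted_log_hr_true)),
      shape = 1
    ) +
    ggplot2::geom_point(
      ggplot2::aes(
        x = exp(.data$observed_log_hr_true),
        colour = .data$inside
      )
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Hazard ratio for overall survival",
      y = "Trial", colour = "Observed inside PI"
    )
}

#' Fixed-horizon sensitivity analysis
#'
#' Re-runs the trial-level analysis after censoring every patient's
#' surrogate observation at `surrogate_horizon` and overall-survival
#' observation at `os_horizon` (e.g. treatment effects on 3-year DFS vs
#' 5-year overall survival). Infinite horizons reproduce the unrestricted
#' analysis exactly.
#'
#' @param observations A long observation tibble containing the surrogate
#'   and true endpoints.
#' @param surrogate,true `endpoint_name` values of the two endpoints.
#' @param surrogate_horizon,os_horizon Censoring horizons in years.
#' @param ... Passed to [fit_trial_regression()].
#' @return A `"surrogacy_trial"` fit on the horizon-censored data.
#' @export
sensitivity_fixed_horizon <- function(observations,
                                      surrogate = "dfs",
                                      true = "os",
                                      surrogate_horizon = 3,
                                      os_horizon = 5,
                                      ...) {
  if (surrogate_horizon > os_horizon) {
    rlang::warn(
      "Surrogate horizon exceeds the overall-survival horizon; the usual design has the surrogate read out earlier."
    )
  }
  max_fu <- max(observations$time)
  if (is.finite(surrogate_horizon) && surrogate_horizon > max_fu) {
    rlang::warn("Surrogate horizon lies beyond the longest follow-up; it has no effect.")
  }
  is_s <- observations$endpoint_name == surrogate
  is_t <- observations$endpoint_name == true
  obs <- dplyr::bind_rows(
    censor_at_horizon(observations[is_s, ], surrogate_horizon),
    censor_at_horizon(observations[is_t, ], os_horizon)
  )
  if (sum(obs$event[obs$endpoint_name == surrogate]) == 0) {
    rlang::abort("No surrogate events remain below the surrogate horizon.")
  }
  fit_trial_regression(trial_summaries(obs, surrogate = surrogate, true = true), ...)
}
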