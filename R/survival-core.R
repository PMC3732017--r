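# Kaplan-Meier curves and per-trial Cox log hazard ratios — the building
# blocks consumed by both surrogacy levels.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survivor function, with tied events
#' handled by simultaneous multiplication. The median is the smallest
#' time at which the estimate drops to 0.5 or below (`NA` if the curve
#' never reaches 0.5).
#'
#' @param observations An observation tibble with `time` (years, >= 0) and
#'   `event` (logical) columns.
#' @return A tibble of class `"km_curve"` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`;
#'   attributes `median` and `n`.
#' @examples
#' km_curve(tibble::tibble(time = 1:4, event = TRUE))
#' @export
km_curve <- function(observations) {
  if (nrow(observations) == 0) {
    rlang::abort("Cannot estimate a survival curve from zero observations.")
  }
  if (any(observations$time < 0)) {
    rlang::abort("Survival times must be >= 0.")
  }
  fit <- survival::survfit(
    survival::Surv(time, event) ~ 1,
    data = observations, conf.type = "none"
  )
  curve <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
  med <- curve$time[curve$survival <= 0.5][1]
  structure(curve,
    class = c("km_curve", class(curve)),
    median = if (is.na(med)) NA_real_ else med,
    n = nrow(observations)
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf(
    "Kaplan-Meier curve: %d subjects, %d events, median %s years\n",
    attr(x, "n"), sum(x$n_event),
    if (is.na(attr(x, "median"))) "not reached" else format(attr(x, "median"))
  ))
  NextMethod()
}

#' Survival at given times from a Kaplan-Meier curve
#'
#' Right-continuous step-function evaluation; returns 1 before the first
#' observed time.
#'
#' @param curve A [km_curve()].
#' @param times Numeric vector of times (years).
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, times) {
  stats::stepfun(curve$time, c(1, curve$survival), right = FALSE)(times)
}

#' Treatment effect as a Cox log hazard ratio
#'
#' Fits the Cox proportional-hazards partial likelihood for a single
#' binary covariate (experimental vs control arm), with the Efron
#' correction for tied event times, and returns the model-based standard
#' error from the inverse observed information.
#'
#' Trials in which all events fall in one arm have a monotone partial
#' likelihood (no finite maximiser); these raise a condition of class
#' `"surroval_monotone_likelihood"` so that callers can exclude the trial
#' explicitly rather than propagate an unstable estimate.
#'
#' @param observations An observation tibble with `time`, `event` and
#'   `arm` (0 control / 1 experimental) columns.
#' @return A one-row tibble: `log_hr`, `se`, `n`, `n_events`.
#' @examples
#' obs <- tibble::tibble(
#'   time = c(1, 2, 3, 4, 1.5, 2.5, 3.5, 4.5),
#'   event = TRUE, arm = rep(0:1, each = 4)
#' )
#' cox_log_hr(obs)
#' @export
cox_log_hr <- function(observations) {
  if (length(unique(observations$arm)) < 2) {
    rlang::abort("Both arms must be present to estimate a hazard ratio.")
  }
  events_by_arm <- tapply(observations$event, observations$arm, sum)
  if (sum(observations$event) == 0) {
    rlang::abort("No events observed; the hazard ratio is not estimable.")
  }
  if (any(events_by_arm == 0)) {
    rlang::abort(
      "All events fall in one arm: the partial likelihood is monotone and no finite log hazard ratio exists.",
      class = "surroval_monotone_likelihood"
    )
  }
  fit <- survival::coxph(
    survival::Surv(time, event) ~ arm,
    data = observations, ties = "efron"
  )
  tibble::tibble(
    log_hr = unname(stats::coef(fit)),
    se = sqrt(unname(stats::vcov(fit)[1, 1])),
    n = nrow(observations),
    n_events = sum(observations$event)
  )
}

#' Per-trial treatment-effect summaries for two endpoints
#'
#' Estimates the Cox log hazard ratio of the treatment on the surrogate
#' endpoint and on the true endpoint within each trial. Trials with a
#' monotone partial likelihood on either endpoint (all events in one arm)
#' are dropped with a warning naming them, since no finite log hazard
#' ratio exists for them.
#'
#' @param observations A long observation tibble (as from
#'   [derive_endpoints()]) containing both endpoints.
#' @param surrogate,true `endpoint_name` values of the surrogate and true
#'   endpoints (default `"os"` as the true endpoint).
#' @return A tibble with one row per retained trial: `trial_id`,
#'   `n_patients`, `log_hr_surrogate`, `se_surrogate`, `log_hr_true`,
#'   `se_true`.
#' @export
trial_summaries <- function(observations, surrogate = "dfs", true = "os") {
  present <- unique(observations$endpoint_name)
  if (!all(c(surrogate, true) %in% present)) {
    rlang::abort(sprintf(
      "Endpoints '%s' and '%s' must both be present (found: %s).",
      surrogate, true, paste(present, collapse = ", ")
    ))
  }
  trials <- unique(observations$trial_id)
  dropped <- character()
  rows <- purrr::map(trials, function(tid) {
    trial_obs <- observations[observations$trial_id == tid, ]
    fit_one <- function(ep) {
      cox_log_hr(trial_obs[trial_obs$endpoint_name == ep, ])
    }
    res <- tryCatch(
      list(s = fit_one(surrogate), t = fit_one(true)),
      surroval_monotone_likelihood = function(cnd) NULL
    )
    if (is.null(res)) {
      dropped <<- c(dropped, as.character(tid))
      return(NULL)
    }
    tibble::tibble(
      trial_id = tid,
      n_patients = res$s$n,
      log_hr_surrogate = res$s$log_hr,
      se_surrogate = res$s$se,
      log_hr_true = res$t$log_hr,
      se_true = res$t$se
    )
  })
  if (length(dropped) > 0) {
    rlang::warn(sprintf(
      "Dropped %d trial(s) with a monotone partial likelihood: %s",
      length(dropped), paste(dropped, collapse = ", ")
    ))
  }
  dplyr::bind_rows(rows)
}

#' @importFrom ggplot2 autoplot
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  steps <- tibble::tibble(
    time = c(0, object$time),
    survival = c(1, object$survival)
  )
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since randomisation", y = "Survival probability")
}
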