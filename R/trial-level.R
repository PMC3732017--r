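# Trial-level surrogacy: weighted regression of treatment effects on the
# true endpoint against treatment effects on the surrogate, weighted by
# trial size; weighted R^2; classical WLS prediction intervals; and the
# surrogate threshold effect.
#
# Weights are normalised to mean 1 internally, so the residual variance
# refers to a trial of average size and every reported quantity is
# invariant to rescaling all weights by a positive constant.

#' Fit the trial-level surrogacy regression
#'
#' Weighted least squares of the log hazard ratio on the true endpoint on
#' the log hazard ratio on the surrogate, with weights proportional to
#' trial size (patients by default, events optionally). The weighted
#' coefficient of determination R^2 = 1 - weighted RSS / weighted TSS
#' measures trial-level surrogacy; its confidence interval is obtained by
#' a trial-level nonparametric bootstrap (percentile).
#'
#' @param summaries A trial-summary tibble from [trial_summaries()]
#'   (columns `trial_id`, `n_patients`, `log_hr_surrogate`, `log_hr_true`;
#'   `n_events` required only for `weight_by = "events"`).
#' @param weight_by Weight trials by `"patients"` (default) or `"events"`.
#' @param intercept Include an intercept (default) or force the line
#'   through the origin.
#' @param n_boot Bootstrap resamples for the R^2 interval; 0 skips it.
#' @param conf_level Confidence level for the R^2 interval.
#' @return An object of class `"surrogacy_trial"`: coefficients,
#'   `sigma2` (residual variance at unit weight), `r_squared` with
#'   `ci_low`/`ci_high`, the normalised weights, `n_trials`, and the
#'   ingredients of prediction intervals (`xtx_inv`, residual df).
#' @examples
#' s <- tibble::tibble(
#'   trial_id = 1:3, n_patients = c(100, 200, 100),
#'   log_hr_surrogate = c(-0.2, 0, 0.4), log_hr_true = c(-0.1, 0, 0.1)
#' )
#' fit_trial_regression(s, n_boot = 0)
#' @export
fit_trial_regression <- function(summaries,
                                 weight_by = c("patients", "events"),
                                 intercept = TRUE,
                                 n_boot = 2000,
                                 conf_level = 0.95) {
  weight_by <- rlang::arg_match(weight_by)
  required <- c("trial_id", "n_patients", "log_hr_surrogate", "log_hr_true")
  if (!all(required %in% names(summaries))) {
    rlang::abort("`summaries` must carry trial sizes and both log hazard ratios.")
  }
  k <- nrow(summaries)
  if (k < 3) {
    rlang::abort(sprintf(
      "At least 3 trials are needed for the trial-level regression (got %d).", k
    ))
  }
  if (!all(is.finite(summaries$log_hr_surrogate)) ||
    !all(is.finite(summaries$log_hr_true))) {
    rlang::abort("Trial summaries must contain finite log hazard ratios.")
  }
  raw_w <- if (weight_by == "patients") {
    summaries$n_patients
  } else {
    summaries$n_events
  }
  if (any(raw_w <= 0)) rlang::abort("Trial weights must be positive.")
  core <- wls_core(
    summaries$log_hr_surrogate, summaries$log_hr_true,
    raw_w, intercept
  )

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    r2_boot <- purrr::map_dbl(seq_len(n_boot), function(i) {
      idx <- sample.int(k, replace = TRUE)
      x <- summaries$log_hr_surrogate[idx]
      if (stats::var(x) < .Machine$double.eps) {
        return(NA_real_)
      }
      wls_core(x, summaries$log_hr_true[idx], raw_w[idx], intercept)$r_squared
    })
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(r2_boot, c(alpha, 1 - alpha), na.rm = TRUE))
  }

  structure(
    c(core, list(
      summaries = summaries,
      weight_by = weight_by,
      intercept = intercept,
      ci_low = ci[1],
      ci_high = ci[2],
      conf_level = conf_level,
      n_trials = k,
      raw_mean_weight = mean(raw_w),
      weighted_mean_size = sum(raw_w * raw_w) / sum(raw_w)
    )),
    class = "surrogacy_trial"
  )
}

# Weighted least squares by the normal equations on weights normalised to
# mean 1. Returns coefficients, sigma2 (unit-weight residual variance),
# weighted R^2 and (X'WX)^{-1} for prediction leverage.
wls_core <- function(x, y, raw_w, intercept) {
  w <- raw_w / mean(raw_w)
  xm <- if (intercept) cbind(1, x) else cbind(x)
  xtwx <- crossprod(xm, w * xm)
  if (abs(det(xtwx)) < .Machine$double.eps * max(abs(xtwx))^ncol(xm)) {
    rlang::abort(
      "Zero variance in the surrogate effects: the slope is unidentifiable."
    )
  }
  xtx_inv <- solve(xtwx)
  beta <- unname(drop(xtx_inv %*% crossprod(xm, w * y)))
  fitted <- drop(xm %*% beta)
  resid <- y - fitted
  df_resid <- length(y) - ncol(xm)
  sigma2 <- if (df_resid > 0) sum(w * resid^2) / df_resid else 0
  # centred TSS with an intercept, uncentred for the origin-forced variant
  ybar <- if (intercept) sum(w * y) / sum(w) else 0
  tss <- sum(w * (y - ybar)^2)
  rss <- sum(w * resid^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  list(
    coefficients = if (intercept) {
      c(intercept = beta[1], slope = beta[2])
    } else {
      c(intercept = 0, slope = beta[1])
    },
    sigma2 = sigma2,
    r_squared = max(0, min(1, r2)),
    residuals = resid,
    fitted = fitted,
    weights = w,
    df_resid = df_resid,
    xtx_inv = xtx_inv
  )
}

#' Prediction interval for the treatment effect on overall survival
#'
#' Classical WLS prediction interval for the true-endpoint log hazard
#' ratio of a new trial with a given surrogate log hazard ratio:
#' point prediction plus/minus the t quantile (residual df) times
#' `sqrt(sigma2 * (1/w0 + leverage))`, where `w0` is the new trial's
#' weight relative to the average trial in the fit. By default the new
#' trial is taken to be of weighted-average size (`w0 = 1`).
#'
#' @param model A fitted [fit_trial_regression()] object.
#' @param log_hr_surrogate Surrogate log hazard ratio(s) at which to
#'   predict.
#' @param level Prediction level in (0, 1).
#' @param weight Optional raw weight (e.g. patient count) of the new
#'   trial; defaults to the weighted mean trial size of the fit.
#' @return A tibble with `log_hr_surrogate`, `fit`, `lwr`, `upr` (log
#'   hazard-ratio scale).
#' @export
prediction_interval <- function(model, log_hr_surrogate, level = 0.95,
                                weight = NULL) {
  stopifnot(inherits(model, "surrogacy_trial"))
  if (level <= 0 || level >= 1) {
    rlang::abort("`level` must lie strictly between 0 and 1.")
  }
  raw_w0 <- if (is.null(weight)) model$weighted_mean_size else weight
  w0 <- raw_w0 / model$raw_mean_weight
  if (w0 <= 0) rlang::abort("The new trial's weight must be positive.")
  b <- model$coefficients
  fit <- b["intercept"] + b["slope"] * log_hr_surrogate
  lev <- purrr::map_dbl(log_hr_surrogate, function(x) {
    x0 <- if (model$intercept) c(1, x) else x
    drop(t(x0) %*% model$xtx_inv %*% x0)
  })
  tcrit <- stats::qt(1 - (1 - level) / 2, df = model$df_resid)
  half <- tcrit * sqrt(model$sigma2 * (1 / w0 + lev))
  tibble::tibble(
    log_hr_surrogate = log_hr_surrogate,
    fit = unname(fit),
    lwr = unname(fit - half),
    upr = unname(fit + half)
  )
}

#' Surrogate threshold effect
#'
#' The minimum treatment effect on the surrogate that predicts a non-zero
#' effect on overall survival: the largest surrogate hazard ratio at
#' which the upper 95% prediction limit for the log hazard ratio on
#' overall survival equals zero. Found by root-finding on the upper
#' prediction limit over surrogate hazard ratios in `bracket`.
#'
#' @param model A fitted [fit_trial_regression()] object with positive
#'   slope (benefit on the surrogate maps to benefit on survival).
#' @param level Prediction level used for the limit (default 0.95).
#' @param bracket Hazard-ratio search bracket (default `c(0.2, 1.5)`).
#' @return A one-row tibble: `ste_hr` (hazard-ratio scale, `NA` when
#'   undefined) and `reason` (`NA` when defined).
#' @examples
#' s <- tibble::tibble(
#'   trial_id = 1:4, n_patients = 100,
#'   log_hr_surrogate = c(-0.4, -0.2, 0, 0.2),
#'   log_hr_true = c(-0.35, -0.2, 0.02, 0.18)
#' )
#' surrogate_threshold_effect(fit_trial_regression(s, n_boot = 0))
#' @export
surrogate_threshold_effect <- function(model, level = 0.95,
                                       bracket = c(0.2, 1.5)) {
  stopifnot(inherits(model, "surrogacy_trial"))
  if (model$coefficients["slope"] <= 0) {
    return(tibble::tibble(
      ste_hr = NA_real_, reason = "effect direction inverted"
    ))
  }
  upper <- function(log_hr_s) {
    prediction_interval(model, log_hr_s, level = level)$upr
  }
  lo <- log(bracket[1])
  hi <- log(bracket[2])
  f_lo <- upper(lo)
  f_hi <- upper(hi)
  if (f_lo > 0) {
    return(tibble::tibble(
      ste_hr = NA_real_,
      reason = "upper prediction limit never reaches 0 in the bracket"
    ))
  }
  if (f_hi < 0) {
    return(tibble::tibble(
      ste_hr = NA_real_,
      reason = "upper prediction limit below 0 throughout the bracket"
    ))
  }
  root <- stats::uniroot(upper, lower = lo, upper = hi, tol = 1e-10)
  tibble::tibble(ste_hr = exp(root$root), reason = NA_character_)
}

#' @export
print.surrogacy_trial <- function(x, ...) {
  cat("Trial-level surrogacy (weighted least squares)\n")
  cat(sprintf(
    "  %d trials, weights: %s%s\n", x$n_trials, x$weight_by,
    if (x$intercept) "" else ", through origin"
  ))
  cat(sprintf(
    "  log HR_OS = %.3f + %.3f * log HR_surrogate, sigma2 = %.4f\n",
    x$coefficients["intercept"], x$coefficients["slope"], x$sigma2
  ))
  ci <- if (is.na(x$ci_low)) {
    ""
  } else {
    sprintf(" (%.0f%% CI %.2f-%.2f)", 100 * x$conf_level, x$ci_low, x$ci_high)
  }
  cat(sprintf(
    "  R^2 = %.3f%s [%s]\n", x$r_squared, ci,
    classify_correlation(x$r_squared)
  ))
  invisible(x)
}

#' @method tidy surrogacy_trial
#' @export
tidy.surrogacy_trial <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(x$coefficients)
  )
}

#' @method glance surrogacy_trial
#' @export
glance.surrogacy_trial <- function(x, ...) {
  ste <- surrogate_threshold_effect(x)
  tibble::tibble(
    r_squared = x$r_squared,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    sigma2 = x$sigma2,
    ste_hr = ste$ste_hr,
    n_trials = x$n_trials
  )
}

#' @method autoplot surrogacy_trial
#' @export
autoplot.surrogacy_trial <- function(object, level = 0.95, ...) {
  s <- object$summaries
  grid <- seq(min(s$log_hr_surrogate), max(s$log_hr_surrogate),
    length.out = 80
  )
  band <- prediction_interval(object, grid, level = level)
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$log_hr_surrogate, ymin = .data$lwr,
        ymax = .data$upr),
      alpha = 0.15
    ) +
    ggplot2::geom_line(
      data = band,
      ggplot2::aes(x = .data$log_hr_surrogate, y = .data$fit)
    ) +
    ggplot2::geom_point(
      data = s,
      ggplot2::aes(
        x = .data$log_hr_surrogate, y = .data$log_hr_true,
        size = .data$n_patients
      ),
      shape = 21
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = "Treatment effect on surrogate (log HR)",
      y = "Treatment effect on overall survival (log HR)",
      size = "Patients"
    )
}
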