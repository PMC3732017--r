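# Individual-level surrogacy: rank correlation between a candidate
# surrogate endpoint and overall survival from censored pairs, via a
# two-stage semiparametric copula model.
#
# Stage 1 estimates each margin's survivor function by Kaplan-Meier.
# Stage 2 plugs the margins into the copula survival representation
# S(x, y) = C(S1(x), S2(y)) and maximises the censored pseudo-likelihood
# in the association parameter theta over the four censoring patterns:
# both events contribute the copula density, a single event the partial
# derivative of C with respect to that margin, and doubly censored pairs
# the copula value itself. theta is mapped to Kendall's tau in closed
# form and to Spearman's rho by quadrature of 12 * int int C du dv - 3.

#' Pair a surrogate endpoint with overall survival
#'
#' Reshapes a long observation table into one row per patient with the
#' surrogate and true-endpoint times and event indicators side by side,
#' the input expected by [fit_copula()].
#'
#' @inheritParams trial_summaries
#' @return A tibble with columns `trial_id`, `patient_id`, `arm`,
#'   `surrogate_time`, `surrogate_event`, `os_time`, `os_event`.
#' @export
surrogacy_pairs <- function(observations, surrogate = "dfs", true = "os") {
  s <- observations[observations$endpoint_name == surrogate, ]
  t <- observations[observations$endpoint_name == true, ]
  if (nrow(s) == 0 || nrow(t) == 0) {
    rlang::abort("Both endpoints must be present in `observations`.")
  }
  dplyr::inner_join(
    dplyr::select(s, "trial_id", "patient_id", "arm",
      surrogate_time = "time", surrogate_event = "event"
    ),
    dplyr::select(t, "patient_id", os_time = "time", os_event = "event"),
    by = "patient_id"
  )
}

# Censored-copula pseudo-log-likelihood at theta; margins are survival
# probabilities already clamped into (0, 1).
copula_pseudo_loglik <- function(theta, log_u, log_v, d_s, d_t, family) {
  ll <- numeric(length(log_u))
  both <- d_s & d_t
  s_only <- d_s & !d_t
  t_only <- !d_s & d_t
  none <- !d_s & !d_t
  if (any(both)) {
    ll[both] <- copula_log_density(log_u[both], log_v[both], theta, family)
  }
  if (any(s_only)) {
    ll[s_only] <- copula_log_du(log_u[s_only], log_v[s_only], theta, family)
  }
  if (any(t_only)) {
    ll[t_only] <- copula_log_dv(log_u[t_only], log_v[t_only], theta, family)
  }
  if (any(none)) {
    ll[none] <- copula_log_cdf(log_u[none], log_v[none], theta, family)
  }
  sum(ll)
}

fit_copula_theta <- function(pairs, family) {
  n <- nrow(pairs)
  clamp <- function(p) pmin(pmax(p, 1 / (2 * n)), 1 - 1e-10)
  s_curve <- km_curve(tibble::tibble(
    time = pairs$surrogate_time, event = pairs$surrogate_event
  ))
  t_curve <- km_curve(tibble::tibble(
    time = pairs$os_time, event = pairs$os_event
  ))
  log_u <- log(clamp(km_survival_at(s_curve, pairs$surrogate_time)))
  log_v <- log(clamp(km_survival_at(t_curve, pairs$os_time)))
  bounds <- .theta_bounds[[family]]
  opt <- stats::optimize(
    function(log_theta) {
      copula_pseudo_loglik(
        exp(log_theta), log_u, log_v,
        pairs$surrogate_event, pairs$os_event, family
      )
    },
    interval = log(bounds), maximum = TRUE, tol = 1e-8
  )
  theta <- exp(opt$maximum)
  at_boundary <- opt$maximum < log(bounds[1]) + 1e-3 ||
    opt$maximum > log(bounds[2]) - 1e-3
  list(theta = theta, loglik = opt$objective, at_boundary = at_boundary)
}

#' Fit the individual-level copula association
#'
#' Estimates the association between a censored surrogate endpoint and
#' overall survival by the two-stage semiparametric copula model, and
#' reports Kendall's tau, Spearman's rho and the individual-level
#' squared rank correlation rho^2 with a patient-level bootstrap
#' percentile confidence interval.
#'
#' @param pairs A pairs tibble from [surrogacy_pairs()] (columns
#'   `surrogate_time`, `surrogate_event`, `os_time`, `os_event`).
#' @param family Copula family: `"clayton"` (lower-tail dependent,
#'   default), `"gumbel"` (upper-tail dependent) or `"independence"`.
#'   The family is a reported modelling choice, not an estimated one.
#' @param n_boot Bootstrap replicates for the rho^2 confidence interval
#'   (resampling patients, refitting margins and copula); 0 skips the
#'   interval.
#' @param conf_level Confidence level of the percentile interval.
#' @param min_pairs Minimum number of pairs required.
#' @return An object of class `"surrogacy_individual"`: a list with
#'   `family`, `theta`, `kendall_tau`, `spearman_rho`, `rho_squared`,
#'   `ci_low`, `ci_high`, `n_pairs`, `loglik`, `at_boundary`.
#' @examples
#' cfg <- simulation_config(n_trials = 2, patients_per_trial = 300,
#'   copula_tau = 0.5, seed = 11)
#' obs <- derive_endpoints(simulate_event_history(cfg), c("dfs", "os"))
#' fit_copula(surrogacy_pairs(obs, "dfs"), n_boot = 0)
#' @export
fit_copula <- function(pairs, family = c("clayton", "gumbel", "independence"),
                       n_boot = 200, conf_level = 0.95, min_pairs = 50) {
  family <- rlang::arg_match(family)
  required <- c("surrogate_time", "surrogate_event", "os_time", "os_event")
  if (!all(required %in% names(pairs))) {
    rlang::abort("`pairs` must carry surrogate and OS times with event flags.")
  }
  if (nrow(pairs) < min_pairs) {
    rlang::abort(sprintf(
      "At least %d pairs are required to fit the copula (got %d).",
      min_pairs, nrow(pairs)
    ))
  }
  if (sum(pairs$surrogate_event) < 1 || sum(pairs$os_event) < 1) {
    rlang::abort("Each margin needs at least one observed event.")
  }

  if (family == "independence") {
    fit <- list(theta = NA_real_, loglik = 0, at_boundary = FALSE)
    tau <- 0
    rho <- 0
  } else {
    fit <- fit_copula_theta(pairs, family)
    tau <- theta_to_tau(fit$theta, family)
    rho <- spearman_from_theta(fit$theta, family)
  }
  if (fit$at_boundary) {
    rlang::warn(paste(
      "Copula association estimate lies at the parameter boundary",
      "(near-comonotone or near-independent pairs); interpret rho^2",
      "as a boundary value."
    ))
  }

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && family != "independence") {
    rho2_boot <- purrr::map_dbl(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(pairs), replace = TRUE)
      bfit <- tryCatch(fit_copula_theta(pairs[idx, ], family),
        error = function(e) NULL
      )
      if (is.null(bfit)) {
        return(NA_real_)
      }
      spearman_from_theta(bfit$theta, family)^2
    })
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(rho2_boot, c(alpha, 1 - alpha),
      na.rm = TRUE
    ))
  }

  structure(
    list(
      family = family,
      theta = fit$theta,
      kendall_tau = tau,
      spearman_rho = rho,
      rho_squared = rho^2,
      ci_low = ci[1],
      ci_high = ci[2],
      conf_level = conf_level,
      n_pairs = nrow(pairs),
      n_boot = if (family == "independence") 0L else as.integer(n_boot),
      loglik = fit$loglik,
      at_boundary = fit$at_boundary
    ),
    class = "surrogacy_individual"
  )
}

#' @export
print.surrogacy_individual <- function(x, ...) {
  cat("Individual-level surrogacy (two-stage copula model)\n")
  cat(sprintf("  family: %s, n = %d pairs\n", x$family, x$n_pairs))
  cat(sprintf(
    "  theta = %.3f, Kendall tau = %.3f, Spearman rho = %.3f\n",
    x$theta, x$kendall_tau, x$spearman_rho
  ))
  ci <- if (is.na(x$ci_low)) {
    ""
  } else {
    sprintf(" (%.0f%% CI %.3f-%.3f)", 100 * x$conf_level, x$ci_low, x$ci_high)
  }
  cat(sprintf(
    "  rho^2 = %.3f%s [%s]\n", x$rho_squared, ci,
    classify_correlation(x$rho_squared)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy surrogacy_individual
#' @export
tidy.surrogacy_individual <- function(x, ...) {
  tibble::tibble(
    term = c("theta", "kendall_tau", "spearman_rho", "rho_squared"),
    estimate = c(x$theta, x$kendall_tau, x$spearman_rho, x$rho_squared)
  )
}

#' @method glance surrogacy_individual
#' @export
glance.surrogacy_individual <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    rho_squared = x$rho_squared,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    kendall_tau = x$kendall_tau,
    n_pairs = x$n_pairs,
    loglik = x$loglik,
    at_boundary = x$at_boundary
  )
}
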