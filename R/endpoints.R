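# Endpoint derivation from raw event histories.
#
# Overall survival: time to death from any cause, censored at last
# follow-up. DFS/PFS: time to first of locoregional event, distant event
# or death, censored at last follow-up. Locoregional control: time to
# first locoregional event, censored at the earliest of distant event,
# death or last follow-up. A tie between a locoregional event and a
# competing event at the same time counts as a locoregional event
# (events take precedence over censoring at equal times).

validate_records <- function(records) {
  required <- c(
    "trial_id", "patient_id", "arm",
    "time_locoregional", "event_locoregional",
    "time_distant", "event_distant",
    "time_death", "event_death",
    "time_last_followup"
  )
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "Subject records are missing columns: ",
      paste(missing, collapse = ", ")
    ))
  }
  if (any(is.na(records$time_last_followup))) {
    rlang::abort("`time_last_followup` must be present for every record.")
  }
  for (ev in c("locoregional", "distant", "death")) {
    tm <- records[[paste0("time_", ev)]]
    fl <- records[[paste0("event_", ev)]]
    if (any(fl & is.na(tm))) {
      rlang::abort(sprintf("Flagged %s events must carry a time.", ev))
    }
    if (any(tm < 0, na.rm = TRUE)) {
      rlang::abort("Event times must be >= 0.")
    }
    if (any(tm[fl] > records$time_last_followup[fl], na.rm = TRUE)) {
      rlang::abort("Observed event times must not exceed last follow-up.")
    }
  }
  invisible(records)
}

observation_tibble <- function(records, endpoint, time, event) {
  tibble::tibble(
    trial_id = records$trial_id,
    patient_id = records$patient_id,
    arm = records$arm,
    endpoint_name = endpoint,
    time = time,
    event = event
  )
}

#' Derive overall survival observations
#'
#' Time from randomisation to death irrespective of cause; patients
#' without an observed death are censored at last follow-up. Earlier
#' non-fatal events do not affect overall survival.
#'
#' @param records A subject-record tibble, as produced by
#'   [simulate_meta_analysis()] or [simulate_event_history()].
#' @return A long observation tibble: `trial_id`, `patient_id`, `arm`,
#'   `endpoint_name`, `time` (years), `event` (logical).
#' @export
derive_overall_survival <- function(records) {
  validate_records(records)
  observation_tibble(
    records, "os",
    dplyr::if_else(records$event_death, records$time_death,
      records$time_last_followup
    ),
    records$event_death
  )
}

#' Derive disease-free / progression-free survival observations
#'
#' Time from randomisation to the first observed event among
#' locoregional, distant and death; censored at last follow-up when no
#' event was observed. A tie among event types is still one first event.
#' `endpoint_name` labels the composite `"dfs"` (operable setting) or
#' `"pfs"` (locally advanced setting); the computation is identical.
#'
#' @inheritParams derive_overall_survival
#' @param endpoint_name `"dfs"` or `"pfs"`.
#' @return A long observation tibble as in [derive_overall_survival()].
#' @export
derive_dfs_pfs <- function(records, endpoint_name = c("dfs", "pfs")) {
  endpoint_name <- rlang::arg_match(endpoint_name)
  validate_records(records)
  first_event <- pmin(
    ifelse(records$event_locoregional, records$time_locoregional, Inf),
    ifelse(records$event_distant, records$time_distant, Inf),
    ifelse(records$event_death, records$time_death, Inf)
  )
  has_event <- is.finite(first_event)
  observation_tibble(
    records, endpoint_name,
    dplyr::if_else(has_event, first_event, records$time_last_followup),
    has_event
  )
}

#' Derive locoregional-control observations
#'
#' Time from randomisation to the first locoregional event; patients
#' with distant progression, who died, or with no documented locoregional
#' event are censored at the date of distant progression, death or last
#' follow-up, whichever comes first. A locoregional event tied with a
#' competing event at the same time is counted as an event.
#'
#' @inheritParams derive_overall_survival
#' @return A long observation tibble as in [derive_overall_survival()].
#' @export
derive_locoregional_control <- function(records) {
  validate_records(records)
  competing <- pmin(
    ifelse(records$event_distant, records$time_distant, Inf),
    ifelse(records$event_death, records$time_death, Inf),
    records$time_last_followup
  )
  loco <- ifelse(records$event_locoregional, records$time_locoregional, Inf)
  is_event <- records$event_locoregional & loco <= competing
  observation_tibble(
    records, "locoregional_control",
    dplyr::if_else(is_event, records$time_locoregional, competing),
    is_event
  )
}

#' Derive several endpoints into one long table
#'
#' Convenience wrapper stacking [derive_overall_survival()],
#' [derive_dfs_pfs()] and [derive_locoregional_control()]; the
#' `"distant"` endpoint (time to distant event, censored at last
#' follow-up, ignoring death truncation) exposes the raw surrogate margin
#' of [simulate_meta_analysis()] for calibration work.
#'
#' @inheritParams derive_overall_survival
#' @param endpoints Character vector drawn from `"os"`, `"dfs"`, `"pfs"`,
#'   `"locoregional_control"`, `"distant"`.
#' @return A long observation tibble with one row per patient-endpoint.
#' @examples
#' cfg <- simulation_config(n_trials = 2, patients_per_trial = 50, seed = 3)
#' derive_endpoints(simulate_event_history(cfg), c("os", "dfs"))
#' @export
derive_endpoints <- function(records,
                             endpoints = c("os", "dfs", "locoregional_control")) {
  endpoints <- unique(match.arg(endpoints,
    c("os", "dfs", "pfs", "locoregional_control", "distant"),
    several.ok = TRUE
  ))
  validate_records(records)
  purrr::map(endpoints, function(ep) {
    switch(ep,
      os = derive_overall_survival(records),
      dfs = derive_dfs_pfs(records, "dfs"),
      pfs = derive_dfs_pfs(records, "pfs"),
      locoregional_control = derive_locoregional_control(records),
      distant = observation_tibble(
        records, "distant",
        dplyr::if_else(records$event_distant, records$time_distant,
          records$time_last_followup
        ),
        records$event_distant
      )
    )
  }) |>
    dplyr::bind_rows()
}

#' Censor observations at a fixed horizon
#'
#' Implements the fixed-horizon sensitivity analyses: observations beyond
#' the horizon are censored at the horizon, observations at or before it
#' (including events exactly at the horizon) are unchanged. Idempotent,
#' and the event set at horizon `h` is a subset of the event set at any
#' larger horizon.
#'
#' @param observations An observation tibble with `time` and `event`
#'   columns (other columns pass through).
#' @param horizon Positive horizon in years; `Inf` is a no-op.
#' @return The observation tibble with `time`/`event` updated.
#' @examples
#' censor_at_horizon(tibble::tibble(time = c(4.2, 2.9), event = TRUE), 3)
#' @export
censor_at_horizon <- function(observations, horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1 || is.na(horizon) ||
    horizon <= 0) {
    rlang::abort("`horizon` must be a single positive number of years.")
  }
  beyond <- observations$time > horizon
  observations$event <- observations$event & !beyond
  observations$time <- pmin(observations$time, horizon)
  observations
}
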