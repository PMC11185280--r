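# Exclusion rules, persistent/absent classification, and display duration.
#
# Three alerts never enter the analysis: alerts triggered by a one-time
# prescription (their response cannot be assessed the next day), alerts that
# require user interaction to resolve their conditions, and alerts first
# displayed in the discharge-day interval (there is no subsequent interval to
# compare against). Every remaining alert is classified by comparing its last
# display interval with the next one: if it vanishes while a triggering
# continuous prescription is still active, it is "absent"; if it is displayed
# up to discharge, or its disappearance coincides with the end of the
# prescription, it is "persistent".

#' Classification policy
#'
#' @param continuity_rule how "continuous prescription" is judged in the
#'   interval after the last display: `"any_chain_active"` (default; absent if
#'   at least one triggering chain is still active), `"all_chains_active"`
#'   (absent only if every triggering chain is still active), or
#'   `"stay_only"` (absent whenever the alert vanishes before discharge,
#'   ignoring prescription continuity).
#' @param interval_hours interval width passed to [build_grid()] (default 24).
#' @return object of class `classification_policy`.
#' @export
classification_policy <- function(continuity_rule = c("any_chain_active",
                                                      "all_chains_active",
                                                      "stay_only"),
                                  interval_hours = 24) {
  continuity_rule <- match.arg(continuity_rule)
  stopifnot(interval_hours > 0)
  structure(list(continuity_rule = continuity_rule,
                 interval_hours = interval_hours),
            class = "classification_policy")
}

#' Display duration of an alert (DDoA)
#'
#' The inclusive count of day intervals between the first and last display:
#' an alert first seen in interval 1 and last seen in interval 4 was
#' displayed for 4 days; an alert seen in a single interval for 1 day.
#'
#' @param first_index,last_index 1-based interval ordinals,
#'   `first_index <= last_index`.
#' @return integer number of days.
#' @export
compute_ddoa <- function(first_index, last_index) {
  if (any(first_index < 1L) || any(first_index > last_index)) {
    stop("compute_ddoa: need 1 <= first_index <= last_index", call. = FALSE)
  }
  as.integer(last_index - first_index + 1L)
}

# presence profile truncated at the first disappearance: absence is terminal,
# a reappearance after a full empty interval is an anomaly, not a new outcome
effective_profile <- function(grid, alert_id) {
  prof <- presence_profile(grid, alert_id)
  reappeared <- length(prof$gap_indices) > 0L
  if (reappeared) {
    prof$last_index <- min(prof$gap_indices) - 1L
  }
  prof$reappeared <- reappeared
  prof
}

outcome_row <- function(alert, first, last, status, reason, absence_index) {
  n <- length(alert$alert_id)
  tibble::new_tibble(list(
    alert_id = alert$alert_id, case_id = alert$case_id,
    alert_type = alert$alert_type, status = status,
    exclusion_reason = reason,
    first_index = as.integer(first), last_index = as.integer(last),
    ddoa_days = compute_ddoa(first, last),
    absence_index = as.integer(absence_index)), nrow = n)
}

#' Apply the three exclusion rules
#'
#' Rules are evaluated in fixed order per alert — one-time trigger, then
#' interactive, then discharge-day first display — and the first matching
#' rule is recorded. Alerts matching none are "analyzed".
#'
#' @param dataset a [cpoe_dataset()].
#' @param grids named list of [build_grid()] results, one per case_id.
#' @return list with `analyzed` (alert tibble with `first_index`,
#'   `last_index`, `reappeared` columns added) and `excluded` (outcome tibble
#'   with `status = "excluded"`).
#' @export
apply_exclusions <- function(dataset, grids) {
  al <- dataset$alerts
  rx <- dataset$prescriptions
  one_time_rx <- rx$rx_id[rx$schedule_kind == "one_time"]

  excluded <- list()
  keep <- logical(nrow(al))
  firsts <- integer(nrow(al))
  lasts <- integer(nrow(al))
  reapp <- logical(nrow(al))

  for (i in seq_len(nrow(al))) {
    grid <- grids[[al$case_id[i]]]
    if (al$alert_id[i] %in% attr(grid, "dropped_alert_ids")) next
    prof <- effective_profile(grid, al$alert_id[i])
    firsts[i] <- prof$first_index
    lasts[i] <- prof$last_index
    reapp[i] <- prof$reappeared
    reason <-
      if (any(al$trigger_rx_ids[[i]] %in% one_time_rx)) "one_time_trigger"
      else if (isTRUE(al$interactive[i])) "interactive"
      else if (prof$first_index == nrow(grid)) "discharge_day_first_display"
      else "none"
    if (reason == "none") {
      keep[i] <- TRUE
    } else {
      excluded[[length(excluded) + 1L]] <-
        outcome_row(al[i, ], prof$first_index, prof$last_index,
                    "excluded", reason, NA_integer_)
    }
  }

  analyzed <- al[keep, ]
  analyzed$first_index <- firsts[keep]
  analyzed$last_index <- lasts[keep]
  analyzed$reappeared <- reapp[keep]
  excluded <- if (length(excluded)) dplyr::bind_rows(excluded) else
    outcome_row(al[0, ], integer(0), integer(0), character(0), character(0),
                integer(0))
  list(analyzed = analyzed, excluded = excluded)
}

#' Classify one analyzed alert as persistent or absent
#'
#' Let `k` be the alert's last display interval (truncated at the first
#' disappearance if the alert ID reappears later). If `k` is the stay's final
#' interval the alert is persistent. Otherwise interval `k + 1` decides:
#' under the default `any_chain_active` rule the alert is absent iff at least
#' one triggering continuous prescription is still active there, and
#' persistent otherwise (its disappearance coincided with the end of the
#' prescription).
#'
#' @param grid the alert's case grid ([build_grid()]).
#' @param chains chain tibble for the case ([build_chains()]).
#' @param alert one-row alert tibble.
#' @param policy a [classification_policy()].
#' @return one-row outcome tibble (`alert_id`, `case_id`, `alert_type`,
#'   `status`, `exclusion_reason`, `first_index`, `last_index`, `ddoa_days`,
#'   `absence_index`).
#' @export
classify_alert <- function(grid, chains, alert,
                           policy = classification_policy()) {
  prof <- effective_profile(grid, alert$alert_id[1])
  k <- prof$last_index
  n_int <- nrow(grid)

  if (k == n_int) {
    return(outcome_row(alert, prof$first_index, k, "persistent", "none",
                       NA_integer_))
  }

  absent <- if (policy$continuity_rule == "stay_only") {
    TRUE
  } else {
    trig <- alert$trigger_rx_ids[[1]]
    in_chain <- vapply(chains$member_rx_ids,
                       function(m) any(trig %in% m), logical(1))
    trig_chains <- chains$chain_id[in_chain]
    active_next <- grid$active_chain_ids[[k + 1L]]
    if (policy$continuity_rule == "any_chain_active") {
      any(trig_chains %in% active_next)
    } else {
      length(trig_chains) > 0L && all(trig_chains %in% active_next)
    }
  }

  if (absent) {
    outcome_row(alert, prof$first_index, k, "absent", "none", k + 1L)
  } else {
    outcome_row(alert, prof$first_index, k, "persistent", "none", NA_integer_)
  }
}

#' Run the full linkage/rasterization/classification pipeline on a dataset
#'
#' Builds prescription chains, rasterizes every stay, applies the exclusion
#' rules, and classifies every analyzed alert. The accounting identity
#' `excluded + absent + persistent = alerts displayed within the stay` holds
#' for every dataset.
#'
#' @param dataset a [cpoe_dataset()].
#' @param policy a [classification_policy()].
#' @param linkage_window follow-up linkage window in seconds (default 600).
#' @return outcome tibble, one row per alert, ordered by `alert_id`, with
#'   attribute `dropped_alert_ids` (alerts displayed entirely outside their
#'   stay) and `reappeared_alert_ids` (IDs that vanished for a full interval
#'   and were redisplayed; classified at the first disappearance).
#' @export
classify_dataset <- function(dataset, policy = classification_policy(),
                             linkage_window = 600) {
  chains <- build_chains(dataset$prescriptions, linkage_window)
  grids <- build_grids(dataset, chains, policy$interval_hours)

  parts <- apply_exclusions(dataset, grids)
  analyzed <- parts$analyzed

  rows <- vector("list", nrow(analyzed))
  for (i in seq_len(nrow(analyzed))) {
    cid <- analyzed$case_id[i]
    rows[[i]] <- classify_alert(grids[[cid]],
                                chains[chains$case_id == cid, ],
                                analyzed[i, ], policy)
  }
  classified <- if (length(rows)) dplyr::bind_rows(rows) else parts$excluded[0, ]

  out <- dplyr::bind_rows(parts$excluded, classified)
  out <- out[order(out$alert_id), ]
  reappeared <- analyzed$alert_id[analyzed$reappeared]
  if (length(reappeared)) {
    message(sprintf("%d alert(s) reappeared after a full empty interval and were classified at the first disappearance: %s",
                    length(reappeared), paste(reappeared, collapse = ", ")))
  }
  structure(out,
            dropped_alert_ids = unlist(lapply(grids, attr, "dropped_alert_ids")),
            reappeared_alert_ids = reappeared)
}

#' Build grids for every case of a dataset
#' @param dataset a [cpoe_dataset()].
#' @param chains [build_chains()] result for all prescriptions.
#' @param interval_hours interval width in hours.
#' @return named list of `interval_grid` objects keyed by case_id.
#' @export
build_grids <- function(dataset, chains, interval_hours = 24) {
  grids <- list()
  for (i in seq_len(nrow(dataset$cases))) {
    cid <- dataset$cases$case_id[i]
    grids[[cid]] <- build_grid(dataset$cases[i, ],
                               dataset$alerts[dataset$alerts$case_id == cid, ],
                               chains[chains$case_id == cid, ],
                               interval_hours)
  }
  grids
}
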