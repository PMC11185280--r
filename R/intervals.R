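# Midnight-anchored rasterization of a stay.
#
# Each stay is tiled into half-open, calendar-day-anchored intervals:
# interval 1 starts at admission, subsequent intervals at each midnight, and
# the last interval ends at discharge. At each boundary, the alerts displayed
# within the preceding interval are identified; intra-day display pauses
# (e.g. ward transfers) are absorbed because presence only requires strictly
# positive overlap somewhere in the interval. The interval width is
# configurable so the lookback window of the method can be varied; only the
# 24-hour default reproduces the published design.

#' Rasterize one stay into day intervals with presence sets
#'
#' @param case one-row tibble (or list) with `case_id`, `admission_ts`,
#'   `discharge_ts`.
#' @param alerts alert tibble restricted to this case (nested, as in
#'   [cpoe_dataset()]). May have zero rows.
#' @param chains chain tibble restricted to this case ([build_chains()]).
#'   May have zero rows.
#' @param interval_hours interval width in hours (default 24). Boundaries are
#'   anchored at the midnight starting the admission day and stepped by this
#'   width; boundaries outside `(admission, discharge)` are clipped away.
#' @return object of class `interval_grid`: a tibble with one row per
#'   interval (`index`, `start_ts`, `end_ts`, list-columns
#'   `displayed_alert_ids` and `active_chain_ids`), with attributes `case_id`,
#'   `admission_ts`, `discharge_ts`, `dropped_alert_ids`.
#' @export
build_grid <- function(case, alerts, chains, interval_hours = 24) {
  stopifnot(interval_hours > 0)
  adm <- case$admission_ts[1]
  dis <- case$discharge_ts[1]
  stopifnot(adm < dis)

  step <- interval_hours * 3600
  anchor <- floor_day(adm)
  k_max <- ceiling(as.numeric(dis - anchor, units = "secs") / step)
  cuts <- anchor + step * seq_len(max(k_max, 1L))
  cuts <- cuts[cuts > adm & cuts < dis]
  bounds <- c(adm, cuts, dis)
  n_int <- length(bounds) - 1L

  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]

  displayed <- rep(list(character(0)), n_int)
  dropped <- character(0)
  if (!is.null(alerts) && nrow(alerts)) {
    for (i in seq_len(nrow(alerts))) {
      seg <- alerts$segments[[i]]
      # clip to the stay; segments entirely outside are dropped with a warning
      hit <- rep(FALSE, n_int)
      any_inside <- FALSE
      for (j in seq_len(nrow(seg))) {
        ov <- spans_overlap(starts, ends, seg$start_ts[j], seg$end_ts[j])
        hit <- hit | ov
        if (any(ov)) any_inside <- TRUE
      }
      if (!any_inside) {
        dropped <- c(dropped, alerts$alert_id[i])
        next
      }
      for (k in which(hit)) {
        displayed[[k]] <- c(displayed[[k]], alerts$alert_id[i])
      }
    }
    if (length(dropped)) {
      warning(sprintf("case '%s': %d alert(s) displayed entirely outside the stay dropped: %s",
                      case$case_id[1], length(dropped),
                      paste(dropped, collapse = ", ")), call. = FALSE)
    }
  }

  active <- rep(list(character(0)), n_int)
  if (!is.null(chains) && nrow(chains)) {
    for (i in seq_len(nrow(chains))) {
      cov <- chains$coverage[[i]]
      hit <- rep(FALSE, n_int)
      for (j in seq_len(nrow(cov))) {
        hit <- hit | spans_overlap(starts, ends, cov$start_ts[j], cov$end_ts[j])
      }
      for (k in which(hit)) {
        active[[k]] <- c(active[[k]], chains$chain_id[i])
      }
    }
  }

  grid <- tibble::tibble(index = seq_len(n_int), start_ts = starts,
                         end_ts = ends,
                         displayed_alert_ids = displayed,
                         active_chain_ids = active)
  structure(grid, class = c("interval_grid", class(grid)),
            case_id = case$case_id[1], admission_ts = adm, discharge_ts = dis,
            dropped_alert_ids = dropped)
}

#' First/last display interval and interior gaps of an alert
#'
#' @param grid an [build_grid()] result.
#' @param alert_id alert to profile; must appear in at least one interval.
#' @return list with `first_index`, `last_index` (extreme interval ordinals
#'   containing the alert) and `gap_indices` (intervals strictly between them
#'   without the alert).
#' @export
presence_profile <- function(grid, alert_id) {
  present <- which(vapply(grid$displayed_alert_ids,
                          function(ids) alert_id %in% ids, logical(1)))
  if (!length(present)) {
    stop(sprintf("alert '%s' was never displayed within this stay", alert_id),
         call. = FALSE)
  }
  first <- present[1]
  last <- present[length(present)]
  list(first_index = first, last_index = last,
       gap_indices = setdiff(seq(first, last), present))
}
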