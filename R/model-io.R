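# Domain model and CSV event-log I/O.
#
# A dataset bundles three tables extracted from a CPOE-CDSS:
#   * cases          -- one row per inpatient stay (admission/discharge)
#   * prescriptions  -- one row per prescription entry; regimen changes are
#                       separate entries so follow-ups can be linked later
#   * alerts         -- one row per alert (nested), carrying its display
#                       segments and the prescriptions that triggered it
#
# On disk, alerts.csv holds one row per display segment; load_dataset()
# merges rows sharing an alert_id into a single nested record.

#' Construct a CPOE alert dataset
#'
#' Bundles the three event tables into a validated `cpoe_dataset`. Most users
#' will call [load_dataset()] (from CSV) or [generate_cpoe()] (synthetic)
#' instead of this constructor.
#'
#' @param cases tibble with columns `case_id`, `admission_ts`, `discharge_ts`.
#' @param prescriptions tibble with columns `rx_id`, `case_id`, `drug_code`,
#'   `route`, `schedule_kind`, `start_ts`, `end_ts`.
#' @param alerts tibble with columns `alert_id`, `case_id`, `alert_type`,
#'   `severity`, `interactive`, and list-columns `trigger_rx_ids` (character
#'   vectors) and `segments` (tibbles with `start_ts`, `end_ts`).
#' @param validate run [validate_dataset()] on the result (default TRUE).
#' @return object of class `cpoe_dataset`: a list with elements `cases`,
#'   `prescriptions`, `alerts`.
#' @export
cpoe_dataset <- function(cases, prescriptions, alerts, validate = TRUE) {
  ds <- structure(
    list(cases = tibble::as_tibble(cases),
         prescriptions = tibble::as_tibble(prescriptions),
         alerts = tibble::as_tibble(alerts)),
    class = "cpoe_dataset")
  if (validate) validate_dataset(ds)
  ds
}

#' @export
print.cpoe_dataset <- function(x, ...) {
  cat("<cpoe_dataset>\n")
  cat("  cases:         ", nrow(x$cases), "\n")
  cat("  prescriptions: ", nrow(x$prescriptions), "\n")
  cat("  alerts:        ", nrow(x$alerts), "\n")
  invisible(x)
}

#' Sort display or coverage spans and merge overlapping/abutting ones
#'
#' Merging never bridges a true gap: a segment starting strictly after the
#' previous one ends stays separate. Gap semantics (ward-transfer pauses vs
#' real disappearance) are decided by the interval engine, not here.
#'
#' @param segments tibble with POSIXct `start_ts`, `end_ts`.
#' @return normalized tibble, sorted, non-overlapping.
#' @export
normalize_segments <- function(segments) {
  if (nrow(segments) <= 1L) {
    return(segments[order(segments$start_ts), c("start_ts", "end_ts")])
  }
  o <- order(segments$start_ts, segments$end_ts)
  s <- segments$start_ts[o]
  e <- segments$end_ts[o]
  keep_s <- s[1]
  keep_e <- e[1]
  for (i in seq_along(s)[-1]) {
    j <- length(keep_s)
    if (s[i] <= keep_e[j]) {            # overlap or abut: extend
      keep_e[j] <- max(keep_e[j], e[i])
    } else {                            # true gap: new segment
      keep_s <- c(keep_s, s[i])
      keep_e <- c(keep_e, e[i])
    }
  }
  tibble::tibble(start_ts = keep_s, end_ts = keep_e)
}

stop_schema <- function(file, col) {
  stop(sprintf("schema error in %s: missing required column '%s'", file, col),
       call. = FALSE)
}

check_columns <- function(df, required, file) {
  for (col in required) if (!col %in% names(df)) stop_schema(file, col)
}

parse_ts_col <- function(x, file, col) {
  out <- parse_ts(x)
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("parse error in %s, row %d: cannot parse %s '%s' as YYYY-MM-DDTHH:MM",
                 file, bad[1], col, x[bad[1]]), call. = FALSE)
  }
  out
}

read_log_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Load and validate the three CPOE event logs
#'
#' Reads `cases.csv`, `prescriptions.csv` and `alerts.csv` (one row per alert
#' display segment; `trigger_rx_ids` semicolon-separated), merges the display
#' segments of each `alert_id` into one nested alert record, and validates
#' referential integrity and all type invariants.
#'
#' @param case_path,rx_path,alert_path paths to the three CSV files.
#' @return a validated [cpoe_dataset()].
#' @export
load_dataset <- function(case_path, rx_path, alert_path) {
  cases_raw <- read_log_csv(case_path)
  check_columns(cases_raw, c("case_id", "admission_ts", "discharge_ts"), case_path)
  cases <- tibble::tibble(
    case_id = cases_raw$case_id,
    admission_ts = parse_ts_col(cases_raw$admission_ts, case_path, "admission_ts"),
    discharge_ts = parse_ts_col(cases_raw$discharge_ts, case_path, "discharge_ts"))

  rx_raw <- read_log_csv(rx_path)
  check_columns(rx_raw, c("rx_id", "case_id", "drug_code", "route",
                          "schedule_kind", "start_ts", "end_ts"), rx_path)
  prescriptions <- tibble::tibble(
    rx_id = rx_raw$rx_id,
    case_id = rx_raw$case_id,
    drug_code = rx_raw$drug_code,
    route = rx_raw$route,
    schedule_kind = rx_raw$schedule_kind,
    start_ts = parse_ts_col(rx_raw$start_ts, rx_path, "start_ts"),
    end_ts = parse_ts_col(rx_raw$end_ts, rx_path, "end_ts"))

  al_raw <- read_log_csv(alert_path)
  check_columns(al_raw, c("alert_id", "case_id", "alert_type", "severity",
                          "interactive", "trigger_rx_ids",
                          "display_start_ts", "display_end_ts"), alert_path)
  al_raw$display_start_ts <- parse_ts_col(al_raw$display_start_ts, alert_path,
                                          "display_start_ts")
  al_raw$display_end_ts <- parse_ts_col(al_raw$display_end_ts, alert_path,
                                        "display_end_ts")

  alerts <- al_raw |>
    dplyr::group_by(.data$alert_id) |>
    dplyr::summarise(
      case_id = .data$case_id[1],
      alert_type = .data$alert_type[1],
      severity = .data$severity[1],
      interactive = tolower(.data$interactive[1]) %in% c("true", "t", "1"),
      trigger_rx_ids = list(sort(unique(unlist(
        strsplit(.data$trigger_rx_ids, ";", fixed = TRUE))))),
      segments = list(normalize_segments(tibble::tibble(
        start_ts = display_start_ts, end_ts = display_end_ts))),
      .groups = "drop")

  cpoe_dataset(cases, prescriptions, alerts)
}

#' Validate a CPOE dataset against the domain invariants
#'
#' Checks ID uniqueness, timestamp ordering (one-time prescriptions may have
#' `start_ts == end_ts`), referential integrity across the three tables, that
#' every alert's triggering prescriptions belong to the alert's own case, and
#' that all prescription/display timestamps fall within
#' `[admission - 1 day, discharge + 1 day]` (boundary records are clipped
#' downstream, not rejected).
#'
#' @param ds a [cpoe_dataset()].
#' @return `ds`, invisibly; stops with an informative error on violation.
#' @export
validate_dataset <- function(ds) {
  cases <- ds$cases
  rx <- ds$prescriptions
  al <- ds$alerts

  if (anyDuplicated(cases$case_id)) {
    stop("validation error: duplicate case_id '",
         cases$case_id[duplicated(cases$case_id)][1], "'", call. = FALSE)
  }
  bad <- which(!(cases$admission_ts < cases$discharge_ts))
  if (length(bad)) {
    stop(sprintf("validation error: case '%s' has discharge_ts <= admission_ts",
                 cases$case_id[bad[1]]), call. = FALSE)
  }

  if (anyDuplicated(rx$rx_id)) {
    stop("validation error: duplicate rx_id '",
         rx$rx_id[duplicated(rx$rx_id)][1], "'", call. = FALSE)
  }
  # one_time prescriptions may collapse to an instant; others need duration
  one_time <- rx$schedule_kind == "one_time"
  bad <- which(rx$start_ts > rx$end_ts |
                 (!one_time & rx$start_ts == rx$end_ts))
  if (length(bad)) {
    stop(sprintf("validation error: prescription '%s' has a non-increasing start/end",
                 rx$rx_id[bad[1]]), call. = FALSE)
  }
  bad_kind <- which(!rx$schedule_kind %in% SCHEDULE_KINDS)
  if (length(bad_kind)) {
    stop(sprintf("validation error: prescription '%s' has unknown schedule_kind '%s'",
                 rx$rx_id[bad_kind[1]], rx$schedule_kind[bad_kind[1]]), call. = FALSE)
  }
  orphan <- which(!rx$case_id %in% cases$case_id)
  if (length(orphan)) {
    stop(sprintf("integrity error: prescription '%s' references unknown case '%s'",
                 rx$rx_id[orphan[1]], rx$case_id[orphan[1]]), call. = FALSE)
  }

  if (nrow(al)) {
    if (anyDuplicated(al$alert_id)) {
      stop("validation error: duplicate alert_id '",
           al$alert_id[duplicated(al$alert_id)][1], "'", call. = FALSE)
    }
    orphan <- which(!al$case_id %in% cases$case_id)
    if (length(orphan)) {
      stop(sprintf("integrity error: alert '%s' references unknown case '%s'",
                   al$alert_id[orphan[1]], al$case_id[orphan[1]]), call. = FALSE)
    }
    bad_type <- which(!al$alert_type %in% ALERT_TYPES)
    if (length(bad_type)) {
      stop(sprintf("validation error: alert '%s' has unknown alert_type '%s'",
                   al$alert_id[bad_type[1]], al$alert_type[bad_type[1]]),
           call. = FALSE)
    }
    rx_case <- stats::setNames(rx$case_id, rx$rx_id)
    for (i in seq_len(nrow(al))) {
      trig <- al$trigger_rx_ids[[i]]
      if (!length(trig)) {
        stop(sprintf("validation error: alert '%s' has no triggering prescriptions",
                     al$alert_id[i]), call. = FALSE)
      }
      unknown <- trig[!trig %in% names(rx_case)]
      if (length(unknown)) {
        stop(sprintf("integrity error: alert '%s' references unknown prescription '%s'",
                     al$alert_id[i], unknown[1]), call. = FALSE)
      }
      if (any(rx_case[trig] != al$case_id[i])) {
        stop(sprintf("integrity error: alert '%s' triggers belong to a different case",
                     al$alert_id[i]), call. = FALSE)
      }
      seg <- al$segments[[i]]
      if (!nrow(seg)) {
        stop(sprintf("validation error: alert '%s' has no display segments",
                     al$alert_id[i]), call. = FALSE)
      }
      if (any(!(seg$start_ts < seg$end_ts))) {
        stop(sprintf("validation error: alert '%s' has a zero- or negative-length display segment",
                     al$alert_id[i]), call. = FALSE)
      }
    }
  }

  # boundary-tolerance window: +-1 day around the stay
  adm <- stats::setNames(cases$admission_ts, cases$case_id)
  dis <- stats::setNames(cases$discharge_ts, cases$case_id)
  day <- 86400
  out <- which(rx$start_ts < adm[rx$case_id] - day | rx$end_ts > dis[rx$case_id] + day)
  if (length(out)) {
    stop(sprintf("validation error: prescription '%s' lies outside its stay's +-1 day window",
                 rx$rx_id[out[1]]), call. = FALSE)
  }
  if (nrow(al)) {
    for (i in seq_len(nrow(al))) {
      seg <- al$segments[[i]]
      cid <- al$case_id[i]
      if (any(seg$start_ts < adm[cid] - day) || any(seg$end_ts > dis[cid] + day)) {
        stop(sprintf("validation error: alert '%s' display segments lie outside its stay's +-1 day window",
                     al$alert_id[i]), call. = FALSE)
      }
    }
  }
  invisible(ds)
}

# ---- result serialization ---------------------------------------------------

OUTCOME_COLS <- c("alert_id", "case_id", "alert_type", "status",
                  "exclusion_reason", "first_index", "last_index",
                  "ddoa_days", "absence_index")

#' Write the analysis result files
#'
#' Writes `outcomes.csv`, `summary.csv`, `pairwise_tests.csv`, `curves.csv`
#' and a JSON run report to `out_dir` and returns the file manifest.
#' `outcomes.csv` round-trips: [read_outcomes()] reproduces the outcome table
#' field-for-field.
#'
#' @param outcomes tibble from [classify_dataset()].
#' @param summary tibble from [summarize_by_type()].
#' @param tests tibble from [pairwise_chi2()].
#' @param curves tibble from [time_to_absence_curves()].
#' @param out_dir output directory, created if needed.
#' @return named character vector of the five file paths (the manifest).
#' @export
write_results <- function(outcomes, summary, tests, curves, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create output directory ", out_dir,
                  call. = FALSE)
  }
  paths <- c(outcomes = file.path(out_dir, "outcomes.csv"),
             summary = file.path(out_dir, "summary.csv"),
             pairwise_tests = file.path(out_dir, "pairwise_tests.csv"),
             curves = file.path(out_dir, "curves.csv"),
             run_report = file.path(out_dir, "run_report.json"))

  readr::write_csv(outcomes[, OUTCOME_COLS], paths[["outcomes"]], na = "")
  readr::write_csv(summary, paths[["summary"]], na = "")
  readr::write_csv(tests, paths[["pairwise_tests"]], na = "")
  readr::write_csv(curves, paths[["curves"]], na = "")

  report <- list(
    n_alerts = nrow(outcomes),
    n_excluded = sum(outcomes$status == "excluded"),
    excluded_by_reason = as.list(table(
      factor(outcomes$exclusion_reason[outcomes$status == "excluded"],
             levels = setdiff(EXCLUSION_REASONS, "none")))),
    n_analyzed = sum(outcomes$status != "excluded"),
    n_absent = sum(outcomes$status == "absent"),
    n_persistent = sum(outcomes$status == "persistent"),
    files = as.list(basename(paths)))
  jsonlite::write_json(report, paths[["run_report"]], auto_unbox = TRUE,
                       pretty = TRUE)
  paths
}

#' Read back an outcomes.csv written by [write_results()]
#' @param path path to `outcomes.csv`.
#' @return outcome tibble with the canonical column types.
#' @export
read_outcomes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    alert_id = readr::col_character(),
    case_id = readr::col_character(),
    alert_type = readr::col_character(),
    status = readr::col_character(),
    exclusion_reason = readr::col_character(),
    first_index = readr::col_integer(),
    last_index = readr::col_integer(),
    ddoa_days = readr::col_integer(),
    absence_index = readr::col_integer()), progress = FALSE)
}
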