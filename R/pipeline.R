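# Batch orchestration: simulate and analyze runs, shared by the R API and
# the command-line script in inst/cli/alertevents.R.

#' Write a dataset back to the three event-log CSVs
#'
#' Inverse of [load_dataset()]: alerts are exploded to one row per display
#' segment with semicolon-separated `trigger_rx_ids`. Output is byte-stable
#' for a given dataset.
#'
#' @param dataset a [cpoe_dataset()].
#' @param out_dir output directory, created if needed.
#' @return named character vector of the three file paths.
#' @export
write_dataset_csvs <- function(dataset, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(cases = file.path(out_dir, "cases.csv"),
             prescriptions = file.path(out_dir, "prescriptions.csv"),
             alerts = file.path(out_dir, "alerts.csv"))

  cases <- dataset$cases
  readr::write_csv(tibble::tibble(case_id = cases$case_id,
                                  admission_ts = format_ts(cases$admission_ts),
                                  discharge_ts = format_ts(cases$discharge_ts)),
                   paths[["cases"]])
  rx <- dataset$prescriptions
  readr::write_csv(tibble::tibble(rx_id = rx$rx_id, case_id = rx$case_id,
                                  drug_code = rx$drug_code, route = rx$route,
                                  schedule_kind = rx$schedule_kind,
                                  start_ts = format_ts(rx$start_ts),
                                  end_ts = format_ts(rx$end_ts)),
                   paths[["prescriptions"]])

  al <- dataset$alerts
  seg_rows <- lapply(seq_len(nrow(al)), function(i) {
    seg <- al$segments[[i]]
    tibble::tibble(alert_id = al$alert_id[i], case_id = al$case_id[i],
                   alert_type = al$alert_type[i], severity = al$severity[i],
                   interactive = ifelse(al$interactive[i], "true", "false"),
                   trigger_rx_ids = paste(al$trigger_rx_ids[[i]], collapse = ";"),
                   display_start_ts = format_ts(seg$start_ts),
                   display_end_ts = format_ts(seg$end_ts))
  })
  flat <- if (length(seg_rows)) dplyr::bind_rows(seg_rows) else
    tibble::tibble(alert_id = character(0), case_id = character(0),
                   alert_type = character(0), severity = character(0),
                   interactive = character(0), trigger_rx_ids = character(0),
                   display_start_ts = character(0),
                   display_end_ts = character(0))
  readr::write_csv(flat, paths[["alerts"]])
  paths
}

#' Simulate a synthetic cohort and write its event logs
#'
#' @param config a [synth_config()].
#' @param out_dir output directory.
#' @return named character vector of the four written files (`cases.csv`,
#'   `prescriptions.csv`, `alerts.csv`, `truth.csv`), invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  sim <- generate_cpoe(config)
  paths <- write_dataset_csvs(sim$dataset, out_dir)
  truth_path <- file.path(out_dir, "truth.csv")
  readr::write_csv(sim$truth, truth_path)
  invisible(c(paths, truth = truth_path))
}

#' Run the full analysis on three event-log CSVs
#'
#' Executes load, follow-up linkage, rasterization, exclusion,
#' classification, summary statistics, and writes the five result files.
#' Stage counts (total, excluded by reason, analyzed, absent, persistent)
#' are reported via `message()`.
#'
#' @param case_path,rx_path,alert_path input CSV paths.
#' @param out_dir output directory for the result files.
#' @param policy a [classification_policy()].
#' @param linkage_window follow-up linkage window in seconds (default 600).
#' @param quiet suppress stage-count messages.
#' @return (invisibly) list with `manifest`, `outcomes`, `summary`, `tests`,
#'   `curves`, `counts`.
#' @export
run_analyze <- function(case_path, rx_path, alert_path, out_dir,
                        policy = classification_policy(),
                        linkage_window = 600, quiet = FALSE) {
  ds <- load_dataset(case_path, rx_path, alert_path)
  outcomes <- classify_dataset(ds, policy, linkage_window)
  summary <- summarize_by_type(outcomes)
  tests <- pairwise_chi2(summary)
  curves <- time_to_absence_curves(outcomes)
  manifest <- write_results(outcomes, summary, tests, curves, out_dir)

  counts <- list(
    total = nrow(outcomes),
    excluded = sum(outcomes$status == "excluded"),
    excluded_one_time = sum(outcomes$exclusion_reason == "one_time_trigger"),
    excluded_interactive = sum(outcomes$exclusion_reason == "interactive"),
    excluded_discharge_day =
      sum(outcomes$exclusion_reason == "discharge_day_first_display"),
    analyzed = sum(outcomes$status != "excluded"),
    absent = sum(outcomes$status == "absent"),
    persistent = sum(outcomes$status == "persistent"))
  if (!quiet) {
    message(sprintf(
      "alerts: %d total; %d excluded (%d one-time, %d interactive, %d discharge-day); %d analyzed: %d absent, %d persistent",
      counts$total, counts$excluded, counts$excluded_one_time,
      counts$excluded_interactive, counts$excluded_discharge_day,
      counts$analyzed, counts$absent, counts$persistent))
  }
  invisible(list(manifest = manifest, outcomes = outcomes, summary = summary,
                 tests = tests, curves = curves, counts = counts))
}
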