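test_that("multi-row alert segments merge into one nested record", {
  dir <- withr::local_tempdir()
  writeLines(c("case_id,admission_ts,discharge_ts",
               "C1,2024-01-01T12:00,2024-01-04T10:00"),
             file.path(dir, "cases.csv"))
  writeLines(c("rx_id,case_id,drug_code,route,schedule_kind,start_ts,end_ts",
               "R1,C1,D1,PO,regular,2024-01-01T12:00,2024-01-04T10:00",
               "R2,C1,D2,IV,regular,2024-01-01T13:00,2024-01-03T10:00"),
             file.path(dir, "prescriptions.csv"))
  writeLines(c(paste0("alert_id,case_id,alert_type,severity,interactive,",
                      "trigger_rx_ids,display_start_ts,display_end_ts"),
               "A1,C1,DDI,severe,false,R1;R2,2024-01-01T13:00,2024-01-02T08:00",
               "A1,C1,DDI,severe,false,R1;R2,2024-01-02T10:00,2024-01-03T10:00"),
             file.path(dir, "alerts.csv"))
  ds <- load_dataset(file.path(dir, "cases.csv"),
                     file.path(dir, "prescriptions.csv"),
                     file.path(dir, "alerts.csv"))
  expect_equal(nrow(ds$alerts), 1L)
  expect_equal(nrow(ds$alerts$segments[[1]]), 2L)  # true gap kept
  expect_setequal(ds$alerts$trigger_rx_ids[[1]], c("R1", "R2"))
})

test_that("schema, referential and invariant violations are rejected with named IDs", {
  dir <- withr::local_tempdir()
  writeLines(c("case_id,admission_ts,discharge_ts",
               "C1,2024-01-01T12:00,2024-01-04T10:00"),
             file.path(dir, "cases.csv"))
  writeLines(c("rx_id,case_id,drug_code,route,schedule_kind,start_ts,end_ts",
               "R1,C1,D1,PO,regular,2024-01-01T12:00,2024-01-04T10:00"),
             file.path(dir, "prescriptions.csv"))
  writeLines(c(paste0("alert_id,case_id,alert_type,severity,interactive,",
                      "trigger_rx_ids,display_start_ts,display_end_ts"),
               "A1,C1,DDI,severe,false,R9,2024-01-01T13:00,2024-01-02T08:00"),
             file.path(dir, "alerts.csv"))
  # alert referencing an unknown prescription names both IDs
  expect_error(load_dataset(file.path(dir, "cases.csv"),
                            file.path(dir, "prescriptions.csv"),
                            file.path(dir, "alerts.csv")),
               "A1.*R9")

  # discharge before admission
  writeLines(c("case_id,admission_ts,discharge_ts",
               "C1,2024-01-04T10:00,2024-01-01T12:00"),
             file.path(dir, "cases2.csv"))
  expect_error(load_dataset(file.path(dir, "cases2.csv"),
                            file.path(dir, "prescriptions.csv"),
                            file.path(dir, "alerts.csv")),
               "discharge_ts <= admission_ts")

  # missing column named in the error
  writeLines(c("case_id,admission_ts", "C1,2024-01-01T12:00"),
             file.path(dir, "cases3.csv"))
  expect_error(load_dataset(file.path(dir, "cases3.csv"),
                            file.path(dir, "prescriptions.csv"),
                            file.path(dir, "alerts.csv")),
               "discharge_ts")

  # unparseable timestamp reported with its row number
  writeLines(c("case_id,admission_ts,discharge_ts",
               "C1,2024-01-01T12:00,2024-01-04T10:00",
               "C2,not-a-time,2024-01-04T10:00"),
             file.path(dir, "cases4.csv"))
  expect_error(load_dataset(file.path(dir, "cases4.csv"),
                            file.path(dir, "prescriptions.csv"),
                            file.path(dir, "alerts.csv")),
               "row 2")
})

test_that("write/load round-trips a synthetic dataset field-for-field", {
  sim <- generate_cpoe(synth_config(n_cases = 8, seed = 11))
  dir <- withr::local_tempdir()
  paths <- write_dataset_csvs(sim$dataset, dir)
  ds2 <- load_dataset(paths[["cases"]], paths[["prescriptions"]],
                      paths[["alerts"]])
  expect_equal(ds2$cases, sim$dataset$cases)
  expect_equal(dplyr::arrange(ds2$prescriptions, rx_id),
               dplyr::arrange(sim$dataset$prescriptions, rx_id))
  a1 <- dplyr::arrange(sim$dataset$alerts, alert_id)
  a2 <- dplyr::arrange(ds2$alerts, alert_id)
  expect_equal(a2$alert_id, a1$alert_id)
  expect_equal(a2$interactive, a1$interactive)
  expect_equal(a2$trigger_rx_ids, a1$trigger_rx_ids)
  # segments equal after normalization on both sides
  expect_equal(lapply(a2$segments, as.data.frame),
               lapply(lapply(a1$segments, normalize_segments), as.data.frame))
})

test_that("validation accepts every generated dataset", {
  for (seed in c(2, 23)) {
    sim <- generate_cpoe(synth_config(n_cases = 15, seed = seed))
    expect_silent(validate_dataset(sim$dataset))
  }
})

test_that("write_results produces the five-file manifest and round-trips outcomes", {
  sim <- generate_cpoe(synth_config(n_cases = 6, seed = 5))
  outcomes <- classify_dataset(sim$dataset)
  summary <- summarize_by_type(outcomes)
  tests <- pairwise_chi2(summary)
  curves <- time_to_absence_curves(outcomes)
  dir <- withr::local_tempdir()
  manifest <- write_results(outcomes, summary, tests, curves, dir)
  expect_length(manifest, 5L)
  expect_setequal(basename(manifest),
                  c("outcomes.csv", "summary.csv", "pairwise_tests.csv",
                    "curves.csv", "run_report.json"))
  expect_true(all(file.exists(manifest)))
  back <- read_outcomes(manifest[["outcomes"]])
  expect_equal(as.data.frame(back), as.data.frame(outcomes)[names(back)],
               ignore_attr = TRUE)
})

test_that("empty outcome list writes header-only outcomes and zero-count summary", {
  empty <- classify_dataset(cpoe_dataset(
    mk_case("C1", "2024-01-01T10:00", "2024-01-03T10:00"),
    mk_rx(character(0), character(0), character(0), character(0), character(0))[0, ],
    mk_alert("x", "C1", "r", list(c("2024-01-01T10:00", "2024-01-01T11:00")))[0, ],
    validate = FALSE))
  dir <- withr::local_tempdir()
  manifest <- write_results(empty, summarize_by_type(empty),
                            pairwise_chi2(summarize_by_type(empty)),
                            time_to_absence_curves(empty), dir)
  expect_equal(nrow(read_outcomes(manifest[["outcomes"]])), 0L)
  s <- readr::read_csv(manifest[["summary"]], show_col_types = FALSE)
  expect_equal(s$n_triggered[s$alert_type == "TOTAL"], 0)
})
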