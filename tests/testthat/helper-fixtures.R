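# In-code fixture builders shared across the suite.

ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")

mk_case <- function(case_id, adm, dis) {
  tibble::tibble(case_id = case_id, admission_ts = ts(adm),
                 discharge_ts = ts(dis))
}

mk_rx <- function(rx_id, case_id, drug, start, end,
                  route = "PO", kind = "regular") {
  tibble::tibble(rx_id = rx_id, case_id = case_id, drug_code = drug,
                 route = route, schedule_kind = kind,
                 start_ts = ts(start), end_ts = ts(end))
}

# segs: list of c(start, end) character pairs
mk_alert <- function(alert_id, case_id, triggers, segs, type = "DDI",
                     severity = "severe", interactive = FALSE) {
  tibble::tibble(
    alert_id = alert_id, case_id = case_id, alert_type = type,
    severity = severity, interactive = interactive,
    trigger_rx_ids = list(triggers),
    segments = list(tibble::tibble(
      start_ts = ts(vapply(segs, `[`, character(1), 1L)),
      end_ts = ts(vapply(segs, `[`, character(1), 2L)))))
}

fig2_paths <- function() {
  dir <- system.file("extdata", "figure2", package = "alertevents")
  list(cases = file.path(dir, "cases.csv"),
       rx = file.path(dir, "prescriptions.csv"),
       alerts = file.path(dir, "alerts.csv"))
}

# A 5-day stay: one alert per published worked example.
# AL1 displayed day 1-4 then gone (trigger continues)   -> absent, DDoA 4
# AL2 displayed day 2 through discharge                 -> persistent, DDoA 4
# AL3 displayed only day 3 (trigger continues)          -> absent, DDoA 1
# AL4 first displayed on the discharge day              -> excluded, DDoA 1
fig2_dataset <- function() {
  p <- fig2_paths()
  load_dataset(p$cases, p$rx, p$alerts)
}

# outcome table reproducing the published per-type analyzed/absent counts
table1_outcomes <- function() {
  counts <- list(DP = c(7643, 3674), DDI = c(2366, 1915), DAI = c(517, 416),
                 PIM = c(499, 199), PE_MDD = c(403, 209))
  rows <- lapply(names(counts), function(ty) {
    n <- counts[[ty]][1]
    n_abs <- counts[[ty]][2]
    status <- c(rep("absent", n_abs), rep("persistent", n - n_abs))
    tibble::tibble(
      alert_id = sprintf("%s-%05d", ty, seq_len(n)),
      case_id = "X", alert_type = ty, status = status,
      exclusion_reason = "none", first_index = 1L,
      last_index = 2L, ddoa_days = 2L,
      absence_index = ifelse(status == "absent", 3L, NA_integer_))
  })
  dplyr::bind_rows(rows)
}

# split every display segment into n abutting sub-segments covering the same
# span (refragmentation; no display time is removed)
refragment_alerts <- function(ds, n = 3L) {
  ds$alerts$segments <- lapply(ds$alerts$segments, function(seg) {
    out <- lapply(seq_len(nrow(seg)), function(j) {
      s <- as.numeric(seg$start_ts[j]); e <- as.numeric(seg$end_ts[j])
      cuts <- s + (e - s) * seq(0, 1, length.out = n + 1L)
      tibble::tibble(
        start_ts = as.POSIXct(cuts[-(n + 1L)], tz = "UTC", origin = "1970-01-01"),
        end_ts = as.POSIXct(cuts[-1L], tz = "UTC", origin = "1970-01-01"))
    })
    dplyr::bind_rows(out)
  })
  ds
}

# carve a short pause out of each day-portion of every display segment,
# strictly inside the portion so presence in that interval is preserved
inject_test_pauses <- function(ds, hole_secs = 600) {
  subtract1 <- function(seg, hs, he) {
    out <- list()
    for (j in seq_len(nrow(seg))) {
      s <- seg$start_ts[j]; e <- seg$end_ts[j]
      if (he <= s || hs >= e) {
        out[[length(out) + 1L]] <- tibble::tibble(start_ts = s, end_ts = e)
      } else {
        if (hs > s) out[[length(out) + 1L]] <- tibble::tibble(start_ts = s, end_ts = hs)
        if (he < e) out[[length(out) + 1L]] <- tibble::tibble(start_ts = he, end_ts = e)
      }
    }
    dplyr::bind_rows(out)
  }
  ds$alerts$segments <- lapply(ds$alerts$segments, function(seg) {
    holes <- list()
    for (j in seq_len(nrow(seg))) {
      s <- seg$start_ts[j]; e <- seg$end_ts[j]
      days <- seq(as.POSIXct(trunc(s, "days"), tz = "UTC"), e, by = 86400)
      for (d in as.numeric(days)) {
        ps <- max(as.numeric(s), d)
        pe <- min(as.numeric(e), d + 86400)
        if (pe - ps >= 4 * hole_secs) {
          mid <- (ps + pe) / 2
          holes[[length(holes) + 1L]] <-
            as.POSIXct(c(mid - hole_secs / 2, mid + hole_secs / 2),
                       tz = "UTC", origin = "1970-01-01")
        }
      }
    }
    for (h in holes) seg <- subtract1(seg, h[1], h[2])
    seg[order(seg$start_ts), ]
  })
  ds
}
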