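# Cohort-level summaries: per-type absence rates with DDoA distributions,
# pairwise chi-square comparisons of absence rates, and discrete
# time-to-absence / persistence-display curves.

type_order <- function(types) {
  known <- intersect(ALERT_TYPES, types)
  c(known, sort(setdiff(types, known)))
}

#' Summarize outcomes per alert type
#'
#' One row per alert type present plus a TOTAL row. Type percentages are of
#' the grand total of analyzed alerts; absence percentages are within each
#' type. DDoA quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7), which can differ slightly from other
#' software's defaults on small strata.
#'
#' @param outcomes outcome tibble from [classify_dataset()]; excluded alerts
#'   are ignored.
#' @return tibble with columns `alert_type`, `n_triggered`, `pct_of_total`,
#'   `n_absent`, `pct_absent`, `ddoa_median`, `ddoa_q1`, `ddoa_q3`,
#'   `ddoa_min`, `ddoa_max`.
#' @export
summarize_by_type <- function(outcomes) {
  an <- outcomes[outcomes$status != "excluded", ]
  n_total <- nrow(an)

  summarize_one <- function(df, label) {
    n <- nrow(df)
    tibble::tibble(
      alert_type = label,
      n_triggered = n,
      pct_of_total = if (n_total > 0) 100 * n / n_total else 0,
      n_absent = sum(df$status == "absent"),
      pct_absent = if (n > 0) 100 * sum(df$status == "absent") / n else NA_real_,
      ddoa_median = if (n > 0) unname(quantile(df$ddoa_days, 0.5)) else NA_real_,
      ddoa_q1 = if (n > 0) unname(quantile(df$ddoa_days, 0.25)) else NA_real_,
      ddoa_q3 = if (n > 0) unname(quantile(df$ddoa_days, 0.75)) else NA_real_,
      ddoa_min = if (n > 0) min(df$ddoa_days) else NA_integer_,
      ddoa_max = if (n > 0) max(df$ddoa_days) else NA_integer_)
  }

  types <- type_order(unique(an$alert_type))
  rows <- lapply(types, function(ty) summarize_one(an[an$alert_type == ty, ], ty))
  dplyr::bind_rows(c(rows, list(summarize_one(an, "TOTAL"))))
}

chi2_2x2 <- function(a, b, c, d) {
  # margins: rows = absent/persistent, cols = type_a/type_b
  tab <- matrix(c(a, b, c, d), nrow = 2,
                dimnames = list(c("absent", "persistent"), NULL))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(stat = 0, p = 1, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(stat = unname(ct$statistic), p = unname(ct$p.value), degenerate = FALSE)
}

#' Pairwise chi-square comparison of absence rates between alert types
#'
#' Pearson chi-square on the 2x2 table (absent/persistent x type pair),
#' df = 1, no continuity correction, two-tailed p. All unordered type pairs
#' of the summary are tested; no multiple-testing correction is applied. A
#' zero margin (both types all absent, or none absent) makes the test
#' undefined: the pair is reported with `chi2_stat = 0`, `p = 1` and
#' `degenerate = TRUE`.
#'
#' @param summary a [summarize_by_type()] table (the TOTAL row is ignored).
#' @return tibble `type_a`, `type_b`, `chi2_stat`, `df`, `p_two_tailed`,
#'   `degenerate`.
#' @export
pairwise_chi2 <- function(summary) {
  s <- summary[summary$alert_type != "TOTAL", ]
  stopifnot(all(s$n_triggered >= 1))
  if (nrow(s) < 2) {
    return(tibble::tibble(type_a = character(), type_b = character(),
                          chi2_stat = numeric(), df = integer(),
                          p_two_tailed = numeric(), degenerate = logical()))
  }
  pairs <- utils::combn(seq_len(nrow(s)), 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    r <- chi2_2x2(s$n_absent[i], s$n_triggered[i] - s$n_absent[i],
                  s$n_absent[j], s$n_triggered[j] - s$n_absent[j])
    tibble::tibble(type_a = s$alert_type[i], type_b = s$alert_type[j],
                   chi2_stat = r$stat, df = 1L, p_two_tailed = r$p,
                   degenerate = r$degenerate)
  })
  dplyr::bind_rows(rows)
}

#' Discrete time-to-absence and persistence-display curves
#'
#' For each alert type and day `t`: the fraction of that type's analyzed
#' alerts that had become absent within `t` intervals of first display
#' (`prop_absent_by_day`, non-decreasing in `t`), and the fraction of
#' persistent alerts still displayed at day `t`
#' (`prop_persistent_displayed`). Simple proportions of the analyzed
#' denominator; no censoring adjustment.
#'
#' @param outcomes outcome tibble from [classify_dataset()].
#' @param max_day last day to tabulate; defaults to the maximum DDoA among
#'   analyzed alerts.
#' @return tibble `alert_type`, `day`, `prop_absent_by_day`,
#'   `prop_persistent_displayed`.
#' @export
time_to_absence_curves <- function(outcomes, max_day = NULL) {
  an <- outcomes[outcomes$status != "excluded", ]
  if (!nrow(an)) {
    return(tibble::tibble(alert_type = character(), day = integer(),
                          prop_absent_by_day = numeric(),
                          prop_persistent_displayed = numeric()))
  }
  if (is.null(max_day)) max_day <- max(an$ddoa_days)
  types <- type_order(unique(an$alert_type))
  rows <- lapply(types, function(ty) {
    df <- an[an$alert_type == ty, ]
    n <- nrow(df)
    days_to_absence <- df$absence_index[df$status == "absent"] -
      df$first_index[df$status == "absent"]
    pers_ddoa <- df$ddoa_days[df$status == "persistent"]
    tibble::tibble(
      alert_type = ty,
      day = seq_len(max_day),
      prop_absent_by_day = vapply(seq_len(max_day),
                                  function(t) sum(days_to_absence <= t) / n,
                                  numeric(1)),
      prop_persistent_displayed = vapply(seq_len(max_day),
                                         function(t) sum(pers_ddoa >= t) / n,
                                         numeric(1)))
  })
  dplyr::bind_rows(rows)
}
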