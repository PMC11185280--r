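mk_outcomes <- function(type, n, n_absent, ddoa = NULL) {
  status <- c(rep("absent", n_absent), rep("persistent", n - n_absent))
  if (is.null(ddoa)) ddoa <- rep(1L, n)
  tibble::tibble(alert_id = sprintf("%s%04d", type, seq_len(n)), case_id = "C",
                 alert_type = type, status = status, exclusion_reason = "none",
                 first_index = 1L, last_index = as.integer(ddoa),
                 ddoa_days = as.integer(ddoa),
                 absence_index = ifelse(status == "absent",
                                        as.integer(ddoa) + 1L, NA_integer_))
}

test_that("per-type summary computes shares, absence rates, and DDoA quartiles", {
  out <- dplyr::bind_rows(mk_outcomes("DDI", 10, 5, c(1, 2, 2, 3, 10, 1, 1, 2, 4, 7)),
                          mk_outcomes("DAI", 10, 2))
  s <- summarize_by_type(out)
  ddi <- s[s$alert_type == "DDI", ]
  expect_equal(ddi$pct_absent, 50)
  expect_equal(ddi$pct_of_total, 50)
  expect_equal(ddi$ddoa_min, 1L)
  expect_equal(ddi$ddoa_max, 10L)
  tot <- s[s$alert_type == "TOTAL", ]
  expect_equal(tot$n_triggered, 20L)
  expect_equal(tot$n_absent, 7L)
  # odd-length median
  s2 <- summarize_by_type(mk_outcomes("DP", 5, 0, c(1, 2, 2, 3, 10)))
  expect_equal(s2$ddoa_median[s2$alert_type == "DP"], 2)
  # excluded alerts never enter the summary
  out_ex <- out
  out_ex$status[1] <- "excluded"
  out_ex$exclusion_reason[1] <- "interactive"
  s3 <- summarize_by_type(out_ex)
  expect_equal(s3$n_triggered[s3$alert_type == "TOTAL"], 19L)
})

test_that("type rows sum to the TOTAL row", {
  sim <- generate_cpoe(synth_config(n_cases = 20, seed = 6))
  s <- summarize_by_type(classify_dataset(sim$dataset))
  types <- s[s$alert_type != "TOTAL", ]
  tot <- s[s$alert_type == "TOTAL", ]
  expect_equal(sum(types$n_triggered), tot$n_triggered)
  expect_equal(sum(types$n_absent), tot$n_absent)
  expect_equal(sum(types$pct_of_total), 100)
})

test_that("pairwise chi-square matches the closed-form 2x2 Pearson statistic", {
  closed_form <- function(a, b, c, d) {
    a <- as.numeric(a); b <- as.numeric(b)
    c <- as.numeric(c); d <- as.numeric(d)
    n <- a + b + c + d
    stat <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
  }
  set.seed(42)
  for (i in 1:50) {
    a <- sample(1:500, 1); b <- sample(1:500, 1)
    c <- sample(1:500, 1); d <- sample(1:500, 1)
    s <- summarize_by_type(dplyr::bind_rows(mk_outcomes("DDI", a + b, a),
                                            mk_outcomes("DAI", c + d, c)))
    t <- pairwise_chi2(s)
    cf <- closed_form(a, b, c, d)
    expect_equal(t$chi2_stat, cf$stat, tolerance = 1e-9)
    expect_equal(t$p_two_tailed, cf$p, tolerance = 1e-9)
    expect_equal(t$df, 1L)
  }
})

test_that("the test is symmetric in the pair and degenerate margins report p = 1", {
  s_ab <- summarize_by_type(dplyr::bind_rows(mk_outcomes("DDI", 30, 12),
                                             mk_outcomes("DAI", 50, 31)))
  s_ba <- summarize_by_type(dplyr::bind_rows(mk_outcomes("DAI", 50, 31),
                                             mk_outcomes("DDI", 30, 12)))
  expect_equal(pairwise_chi2(s_ab)$p_two_tailed, pairwise_chi2(s_ba)$p_two_tailed)

  # identical tables: no difference at all
  s_same <- summarize_by_type(dplyr::bind_rows(mk_outcomes("DDI", 40, 10),
                                               mk_outcomes("DAI", 40, 10)))
  t_same <- pairwise_chi2(s_same)
  expect_equal(t_same$chi2_stat, 0)
  expect_equal(t_same$p_two_tailed, 1)

  # zero margin: nothing absent in either type
  s_zero <- summarize_by_type(dplyr::bind_rows(mk_outcomes("DDI", 40, 0),
                                               mk_outcomes("DAI", 40, 0)))
  t_zero <- pairwise_chi2(s_zero)
  expect_true(t_zero$degenerate)
  expect_equal(t_zero$p_two_tailed, 1)

  # all 10 unordered pairs for five types
  s5 <- summarize_by_type(dplyr::bind_rows(
    lapply(c("DP", "DDI", "DAI", "PIM", "PE_MDD"),
           function(ty) mk_outcomes(ty, 30, 11))))
  expect_equal(nrow(pairwise_chi2(s5)), 10L)
})

test_that("time curves agree with a brute-force per-day recount", {
  brute_force <- function(outcomes, max_day) {
    an <- outcomes[outcomes$status != "excluded", ]
    rows <- list()
    for (ty in unique(an$alert_type)) {
      sub <- an[an$alert_type == ty, ]
      for (t in seq_len(max_day)) {
        n_abs <- 0L; n_disp <- 0L
        for (i in seq_len(nrow(sub))) {
          if (sub$status[i] == "absent" &&
              (sub$absence_index[i] - sub$first_index[i]) <= t) {
            n_abs <- n_abs + 1L
          }
          if (sub$status[i] == "persistent" && sub$ddoa_days[i] >= t) {
            n_disp <- n_disp + 1L
          }
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          alert_type = ty, day = t,
          prop_absent_by_day = n_abs / nrow(sub),
          prop_persistent_displayed = n_disp / nrow(sub))
      }
    }
    dplyr::bind_rows(rows)
  }
  sim <- generate_cpoe(synth_config(n_cases = 25, seed = 19))
  out <- classify_dataset(sim$dataset)
  max_day <- max(out$ddoa_days[out$status != "excluded"])
  got <- time_to_absence_curves(out, max_day)
  want <- brute_force(out, max_day)
  j <- dplyr::left_join(got, want, by = c("alert_type", "day"))
  expect_equal(j$prop_absent_by_day.x, j$prop_absent_by_day.y)
  expect_equal(j$prop_persistent_displayed.x, j$prop_persistent_displayed.y)
  # cumulative absence never decreases
  for (ty in unique(got$alert_type)) {
    expect_true(all(diff(got$prop_absent_by_day[got$alert_type == ty]) >= 0))
  }
})

test_that("degenerate curve inputs behave: immediate absence and no absence", {
  imm <- mk_outcomes("DDI", 6, 6)        # all absent one interval after first
  c1 <- time_to_absence_curves(imm, 3)
  expect_equal(c1$prop_absent_by_day, rep(1, 3))
  none <- mk_outcomes("DDI", 6, 0)
  c2 <- time_to_absence_curves(none, 3)
  expect_equal(c2$prop_absent_by_day, rep(0, 3))
})
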