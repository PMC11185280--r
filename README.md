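# alertevents

Automated event analysis of persistent and absent medication alerts in
CPOE/CDSS event logs.

## The problem

Many European computerized physician order entry (CPOE) systems present
clinical decision support alerts **passively and noninterruptively**: the
prescriber opens a side window listing current alerts, but is never forced
to accept or override anything. No in-dialog acceptance data exist, so alert
acceptance must be estimated indirectly — by *event analysis*: watching the
medication record for changes that follow alert display. Done manually this
is prohibitively slow for longitudinal inpatient data.

`alertevents` automates it. It is intended for pharmacoepidemiologists and
CDSS teams who can export three event logs from their system — patient
cases, prescriptions, and alert display records — and want cohort-level
absence/persistence rates per alert type.

## The method

1. **Follow-up linkage.** Prescription entries of the same drug and
   administration route whose end/start gap is at most *w* = 10 minutes are
   chained into one *continuous prescription* (regimen changes are separate
   entries in the log, so a dose reduction looks like end + immediate
   restart).
2. **Rasterization.** Each stay is tiled into half-open, midnight-anchored
   24-hour intervals `[t_i, t_{i+1})` — interval 1 starts at admission, the
   last ends at discharge. An alert (identified by its unique alert ID) or a
   chain is *present* in an interval iff it overlaps it with positive
   duration. Intra-day display pauses (ward transfers) are absorbed by the
   interval width.
3. **Exclusion.** Alerts are excluded if triggered by a one-time
   prescription, if they require user interaction, or if first displayed in
   the discharge-day interval (no subsequent interval to compare with).
4. **Classification.** Let *k* be an analyzed alert's last display interval.
   If *k* is the final interval, the alert is **persistent**. Otherwise look
   at interval *k*+1: if a triggering continuous prescription is still
   active there, the alert vanished while therapy continued — **absent**
   (the proxy for acceptance); if the prescription ended with the display,
   it is **persistent**.
5. **Display duration.** `DDoA = last − first + 1` intervals (days).
6. **Statistics.** Per-type summary (counts, % absent, DDoA median/IQR/
   range), all pairwise Pearson chi-square tests on 2×2 absent/persistent
   tables (df = 1, no continuity correction, two-tailed), and discrete
   time-to-absence / persistence-display proportion curves.

A seeded synthetic-cohort generator (`synth_config()` / `generate_cpoe()`)
produces CSV logs with ground-truth labels, so the whole pipeline can be
validated end-to-end without hospital data.

## Worked example

The package ships a five-day stay with four alerts
(`inst/extdata/figure2/`): alert AL1 displayed day 1–4, AL2 from day 2 to
discharge, AL3 on day 3 only, AL4 first on the discharge day.

```r
library(alertevents)
fx <- system.file("extdata", "figure2", package = "alertevents")
res <- run_analyze(file.path(fx, "cases.csv"),
                   file.path(fx, "prescriptions.csv"),
                   file.path(fx, "alerts.csv"), "fig2-out")
#> alerts: 4 total; 1 excluded (0 one-time, 0 interactive, 1 discharge-day);
#> 3 analyzed: 2 absent, 1 persistent
as.data.frame(res$outcomes)
#>  alert_id case_id alert_type     status            exclusion_reason first_index last_index ddoa_days absence_index
#>       AL1      F2        DDI     absent                        none           1          4         4             5
#>       AL2      F2        DAI persistent                        none           2          5         4            NA
#>       AL3      F2     PE_MDD     absent                        none           3          3         1             4
#>       AL4      F2         DP   excluded discharge_day_first_display           5          5         1            NA
```

AL1 was shown for 4 days and vanished while its trigger prescription ran on
(absent, detected in interval 5); AL2 persisted to discharge (DDoA 4); AL3
was shown a single day (DDoA 1, absent in interval 4); AL4 cannot be
evaluated and is excluded.

A command-line front end wraps the same pipeline:

```sh
Rscript inst/cli/alertevents.R simulate --n-cases 50 --seed 1 --out sim/
Rscript inst/cli/alertevents.R analyze --cases sim/cases.csv \
    --rx sim/prescriptions.csv --alerts sim/alerts.csv --out run1/ \
    --continuity-rule any --interval-hours 24 --linkage-minutes 10
Rscript inst/cli/alertevents.R report --outcomes run1/outcomes.csv
```

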