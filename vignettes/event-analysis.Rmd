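---
title: "Event analysis of persistent and absent medication alerts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event analysis of persistent and absent medication alerts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alertevents)
```

## The estimation problem

In a CPOE whose decision-support alerts are passive and noninterruptive, a
prescriber is never asked to accept or override an alert, so no in-dialog
acceptance record exists. The only observable trace of a *successful* alert
is an event in the medication record: the risk constellation is edited away
(dose reduced, duplicate stopped, drug switched route), and the alert —
which the CDSS recomputes continuously — stops being displayed while the
underlying prescription itself carries on.

`alertevents` operationalizes that trace. Its unit of inference is the
**alert ID**: each risk constellation keeps a stable identifier for as long
as it exists, so comparing the set of IDs displayed in consecutive time
windows reveals appearance and disappearance without interpreting any
free-text documentation.

### Model assumptions

* Alerts are reviewed regularly, and an alert disappearing during an active
  prescription reflects a prescription change responsive to the alert. This
  overestimates acceptance when therapy changes for unrelated clinical
  reasons; the method deliberately does not attempt to distinguish the two,
  and its output should be read as an upper bound on acceptance.
* Display interruptions shorter than the interval width are administrative
  (ward transfers pause prescriptions and re-display alerts hours later),
  not clinical signal.
* Prescription-level only: whether a drug was administered is out of scope.

## The procedure

**Follow-up linkage.** Regimen changes are logged as separate prescription
entries. Entries of the same case, drug code and route whose end-to-start
gap lies in `[0, w]` are chained into one *continuous prescription*; the
default `w` is 10 minutes. The boundary is inclusive — a gap of exactly 10
minutes links — because the window's purpose is to ignore administrative
pauses, and an exclusive reading would split on the very gaps it exists to
bridge. When one ending entry has several candidate successors inside the
window, the earliest-starting one continues the chain and the rest open new
chains (processing in start-time order makes this deterministic under input
shuffling). Overlapping entries of the same drug/route are duplicate
therapy — exactly what DP alerts flag — and are never chained.

**Rasterization.** Each stay is tiled into half-open intervals
`[t_i, t_{i+1})`: interval 1 starts at admission, every later interval at a
midnight, the last ends at discharge, so first and last intervals may be
shorter than 24 h. Presence of an alert (or chain) in an interval requires
strictly positive overlap; a segment ending exactly at a midnight belongs to
the earlier interval only. Timestamps are wall-clock at minute precision,
held in a fixed offset-free representation so midnight arithmetic is exact;
daylight-saving shifts are out of scope. The interval width is a parameter
(`interval_hours`, default 24) because the lookback window is the method's
main tuning knob: shorter intervals detect faster reactions but mistake
ward-transfer pauses for absence. Only the 24-hour default is exercised by
the shipped validation.

**Exclusions,** evaluated per alert in fixed order, first match recorded:

1. *one-time trigger* — a single-administration order cannot be re-assessed
   the next day;
2. *interactive* — alerts requiring user interaction have their own
   resolution pathway;
3. *discharge-day first display* — no subsequent interval exists to compare
   with.

The order mirrors the order in which the corresponding counts are
conventionally reported; it only matters for the attributed reason, never
for the analyzed set.

**Classification.** Let `k` be the alert's last display interval. `k` equal
to the stay's final interval means *persistent*. Otherwise interval `k+1`
decides, governed by `continuity_rule`:

* `any_chain_active` (default): *absent* iff at least one triggering chain
  is active in `k+1`. This is the right default because the paradigmatic
  absence event — dose reduction resolving an overdose alert — leaves
  exactly one continuous chain running; requiring all chains would turn
  most resolved two-drug (DDI/DP) alerts into persistent ones.
* `all_chains_active`: stricter; *absent* only if every triggering chain
  survives.
* `stay_only`: ignores prescriptions entirely.

The absent sets are provably nested (`all ⊆ any ⊆ stay_only`), which the
test suite asserts on simulated cohorts.

**Display duration.** `DDoA = k − first + 1` intervals, an inclusive count,
so a single-interval alert has DDoA 1 by construction.

**Reappearance.** An alert ID absent for one or more full intervals and
then redisplayed is classified at its *first* disappearance
(`absence_index` = first empty interval, `last_index` = last pre-gap
interval); the reappearance is surfaced as an anomaly rather than a second
outcome. Absence is treated as terminal because the interval width already
absorbed every legitimate pause; a full-interval gap under a still-active
prescription is either a new constellation (new ID in practice) or a data
artifact worth flagging.

**Statistics.** The per-type table reports analyzed counts, type shares of
the grand total, absence shares within type, and DDoA median/quartiles/range
with quartiles by linear interpolation of order statistics
(`stats::quantile` type 7); other software's quartile conventions can differ
by up to a day on small strata. Pairwise absence-rate comparisons use the
Pearson chi-square on the 2×2 table, df 1, *no* continuity correction, two
tailed, unadjusted for multiplicity; a zero margin is reported as degenerate
with p = 1 rather than NaN. The time curves are simple proportions of the
analyzed denominator — the fraction absent within *t* intervals of first
display and the fraction of persistent alerts still displayed at day *t* —
not censoring-adjusted product-limit estimates; with discharge acting as
administrative censoring the simple proportion understates late absence,
which is acceptable for the curves' descriptive purpose and is labelled as
such in the output.

## The synthetic cohort generator

`generate_cpoe()` exists so that every stage has a ground-truth oracle. Per
case it draws a length of stay as `1 + NB(size 2, μ)` with `μ` solved at run
time so the median equals `los_median_days` (default 7 days); admission and
discharge times fall in working hours, which guarantees every stay spans at
least two intervals and keeps boundary intervals non-degenerate. Alert
counts per type are Poisson with per-type rates defaulting to the observed
cohort composition (DP 5.60, DDI 1.73, DAI 0.38, PIM 0.37, PE-MDD 0.29 per
case, i.e. ~8.4 alerts/case); each alert is one-time-triggered with
probability 0.163, discharge-day-onset with 0.019, interactive with 0
(set `interactive_fraction` to exercise that rule), otherwise analyzed and
absent with the type's `p_absent` (defaults 48.1/80.9/80.5/39.9/51.9%).
Displayed duration is `1 + Geom(0.25)` days capped by the stay, putting the
median DDoA near the observed 3 days.

Truth labels are *realized at interval granularity*: an absent alert's
display stops exactly at an interval boundary and its trigger chain remains
active through the whole following interval; a persistent alert either runs
to discharge or ends strictly inside its last display interval with its
chain. Sub-interval ambiguity is deliberately never generated, so the
default policy must recover the labels exactly — a 100% agreement check,
not a statistical one. Trigger chains are realized as one or two
prescription entries with gaps of 1–10 minutes (exercising linkage);
DDI/DP alerts carry two trigger drugs; intra-day display pauses are carved
out of alert-days with probability `pause_rate` and never span a midnight.

What the generator does **not** emulate: realistic drug identities or
co-prescription structure (every trigger gets a fresh drug code, so linkage
is never confounded across alerts), severity-dependent behaviour,
sub-interval timing signal, or alerts whose ID changes mid-episode. Passing
tests therefore demonstrate the *mechanics* — linkage, rasterization,
exclusion, classification, accounting — under the stated interval-aligned
conditions, not performance on messy production exports where, e.g., the
same drug may trigger overlapping constellations.

## Numerical and degenerate-input choices

* Half-open intervals everywhere; zero-duration overlap is never presence,
  so an instantaneous one-time prescription is never "active".
* The ±1-day tolerance window around a stay admits boundary records, which
  the grid then clips; display segments entirely outside the stay are
  dropped with a warning.
* Chain linkage ties (several open chains eligible for one entry) resolve
  to the chain ending closest to the entry's start, then to the oldest
  chain — deterministic under row shuffling.
* Empty inputs degrade gracefully: header-only CSVs, a zero-count TOTAL
  row, empty curve and test tables.

## Validation problem sizes

The shipped suite validates on simulated cohorts of 10–60 cases across
multiple seeds (plus one 500-case cohort for the law-of-large-numbers check
on exclusion shares and one 400-case check of the median length of stay),
alongside the packaged five-day worked example. These sizes give thousands
of alerts per run, ample for exact structural assertions (recovery,
accounting, invariance) whose truth does not depend on scale.

## Known limitations

* Absence is an upper bound on acceptance; no causal claim is possible
  without a control group.
* Single-ID reasoning assumes the CDSS keeps alert IDs stable across
  recomputations; systems that reissue IDs need a pre-mapping step.
* Calendar-day anchoring makes the first interval short for evening
  admissions, slightly accelerating first-day absence detection relative to
  admission-anchored windows.
* No administration-level (MAR) verification.
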