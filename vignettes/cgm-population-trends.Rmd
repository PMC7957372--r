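---
title: "Methods: population-scale CGM trend analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-scale CGM trend analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmtrends)
```

## The analysis

`cgmtrends` studies how glycemic control in a large population of real-time
CGM users changed between two 8-week observation windows — a prepandemic
interval (Jan 6 – Mar 1, 2020) and an early intrapandemic interval
(Apr 20 – Jun 14, 2020) — and how that change distributes across
geography, income, and device tenure. The design is a paired pre/post
comparison: every metric is computed per user per window, the unit of
analysis is the within-user change, and population statements are means
over users (never pooled readings), which is why trajectory displays carry
SEM = SD/√n error bars across users.

Four conventions do a lot of quiet work and are worth stating:

- **Reading-weighted metrics.** Each sensor value counts equally. At the
  G6's near-uniform 5-minute cadence this coincides with time-weighting,
  and it matches a data model in which "uploaded sensor glucose values" are
  the unit of observation.
- **Band endpoints.** The target band 70–180 mg/dL is closed on both ends;
  below-range bands use a strict `<` and above-range bands a strict `>`.
  This is the consensus-report convention, and it is also the only choice
  under which TIR + TBR70 + TAR180 partitions 100% exactly — an identity
  the test suite asserts on every input.
- **One reference timezone.** Timestamps are UTC instants and all day and
  week boundaries are evaluated in UTC. The cohort spans four US time
  zones and no published rule exists for day boundaries; a single global
  convention keeps daily counts deterministic and reproducible. Day
  boundaries shift by a few hours relative to local midnight, which is
  immaterial for 8-week window metrics and slightly blurs day-level
  missingness patterns.
- **Weeks are anchored at the window start.** Jan 6, 2020 is a Monday, so
  window weeks coincide with calendar Mon–Sun weeks for the canonical
  windows, and weekly trajectories use the same anchoring.

## Inclusion filtering

A user enters the paired cohort when all five criteria hold: first upload
on or before Jan 1, 2020 (inclusive); mobile-app viewer; at least one
reading in each month Jan–Jun 2020; and the data-density rule — ≥200
readings per day on ≥4 days per week — in both windows. The density rule's
"per week" is ambiguous between *every week individually* and *on average
over the window*; `density_rule(scope = )` implements both, defaulting to
the per-week reading because it is the strictest literal one. Which
reading the original analysis used is unknown; on synthetic cohorts the
two agree for all but users hovering exactly at the margin. The relaxed
variant (`enabled = FALSE`), applied automatically for the late-summer
window (Jun 15 – Aug 9, 2020), reduces inclusion to the three non-density
criteria.

Filtering is monotone by construction — weakening the rule can only add
users — and `filter_cohort()` emits a per-user report whose reasons
(`late_start`, `not_mobile`, `missing_month`, `density_pre`,
`density_post`) make every exclusion auditable.

## Metrics and the paired comparison

Per user and window: TIR, TBR<70, TBR<54, TAR>180, TAR>250 (all % of
readings), mean glucose, SD, CV = 100·SD/mean (n−1 SD), and
GMI(%) = 3.31 + 0.02392 × mean glucose. GMI is returned at full precision
so its affine structure is exact; reporting rounds to 2 decimals. Goal
flags use TIR ≥ 70% and TAR>250 < 5%.

The paired analysis takes the inner join of the two per-user metric
tables, so mean(Δ) equals the difference of cohort means exactly. Changes
of at least 5 TIR points (inclusive) in either direction are "clinically
meaningful"; "improved" means strictly Δ > 0, with ties counted as not
improved. The dependent t-test is computed from first principles
(t = mean/SE, df = n−1) and is held to 1e-9 agreement with
`stats::t.test` in the tests; the package applies no multiple-testing
correction across strata, mirroring the original analysis.

## Stratification and the burden correlation

County summaries keep counties with at least `min_users` (default 200)
paired users and correlate the fraction of meaningfully improved users
with log county deaths (cumulative, as of a snapshot date, default
May 21, 2020). Natural log is used; Pearson r is invariant to the log
base and to positive scaling of deaths, so the choice only matters for
axis labels. Zero-death counties are excluded rather than offset by +1:
an offset changes r, whereas exclusion matches a snapshot date at which
candidate counties had deaths.

Income bands default to <$50k, $50–100k, $100–150k, >$150k — only the
$150k upper edge is anchored in the published description; interior edges
are package defaults. Tenure bands default to <13, 13–24, 25–36, ≥37
months, with only "≥37" anchored. Confidence intervals are normal
approximations (mean ± 1.96·SD/√n); at the strata sizes of interest
(hundreds to tens of thousands) the difference from a t interval is
negligible. The state→region map for the five CDC Centers of Excellence
regions is a *synthetic reconstruction*: the hubs (Colorado, Minnesota,
New York, Tennessee, Washington) and the per-region state counts match the
published description, but the membership of non-hub states is
approximated by geography because the authoritative table is not
redistributable. Regional results on real data should substitute the
exact map; `assign_region()` accepts any `state, region` table.

New York City is modeled as the union of its five county FIPS codes
(`nyc_fips()`).

## The synthetic cohort generator

Real uploader streams are proprietary, so the generator is a first-class,
tested module that emulates the population's statistical structure. Per
user $i$ in county $c(i)$ with zip income $\mathrm{inc}(i)$ (standardized
log income $z_i$):

- baseline mean glucose
  $m_i = \mu_0 - \beta_{\mathrm{inc}} z_i + \varepsilon_i$,
  $\varepsilon_i \sim N(0, \sigma_b^2)$, floored at 60 mg/dL;
- a pandemic step shift applied to all readings on/after the stay-at-home
  date (default Mar 19, 2020):
  $s_i = \frac{m_i}{\mu_0}\left(\delta + b_{c(i)} -
  \beta_{\mathrm{shift}} z_i + \eta_i\right)$,
  $\eta_i \sim N(0, \sigma_s^2)$, where $b_c$ is −(burden coupling) ×
  standardized log county deaths;
- readings every 5 minutes, lognormal around the (shifted) mean with
  constant within-user CV and AR(1) log-residuals (default ρ = 0.95),
  rounded to integers and clamped to the sensor-reportable 40–400 mg/dL;
- whole-day dropout and within-day slot missingness; a tenure mixture
  guaranteeing a ≥37-month stratum; small fractions of late starters and
  receiver-only users so the filters have work to do.

Three structural choices depart from the most naive model, and matter:

1. **Constant within-user CV rather than constant mg/dL SD.**
   `within_user_sd` (default 55 mg/dL) is the SD *at the population mean*,
   i.e. a within-user CV of ≈32%, which is typical of real CGM traces.
2. **Level-proportional shifts.** The applied shift scales with
   $m_i/\mu_0$, so a population disturbance moves high-glucose users more
   in absolute terms; its expectation stays at $\delta$.
3. **CV–shift coupling** (`cv_shift_coupling`, default 1): a user's
   improvement also reduces their variability proportionally.

The reason: under a pure location shift with level-independent spread, the
population-average dTIR/d(mean glucose) is approximately zero — users with
low means lose range time at the 70 mg/dL edge as fast as high-mean users
gain it at 180 — so a −3.1 mg/dL glucose change and a +2.0-point TIR
change cannot coexist. In the real population the improvement was
concentrated in hyperglycemia (the >250 mg/dL trajectories fell while the
<54 mg/dL trajectories barely moved), which is exactly what the CV
coupling produces.

Defaults were calibrated **once**, from a closed-form sweep of the model's
marginal TIR (the lognormal band probability integrated over the
between-user distribution), against the published population statistics:
mean glucose 173.3 (SD 35.9) → 170.2 mg/dL, TIR 59.0 (20.1)% with paired
change ≈ +2.0 (SD ≈ 10). The frozen defaults reproduce, on a 2,000-user
cohort: pre TIR ≈ 60 (SD ≈ 19), ΔTIR ≈ +2.0 (SD ≈ 9.3), Δglucose ≈ −2.9,
ΔCV ≈ −0.6. They are stored in `generator_config()` and documented as
calibrated, not fitted; the published 59.4% improver fraction slightly
exceeds what any Gaussian change distribution implies, so matching it
exactly is explicitly not a target.

What the generator does *not* emulate: meals, insulin dosing, diurnal and
weekday cycles, sensor warm-up and compression artifacts, drift in
missingness over time, or migration between counties. Passing tests
therefore demonstrate that the pipeline's statistics are correct and
recover known parameters under a realistic marginal structure — not that
the pipeline's epidemiological conclusions would survive those real-data
complications.

## Numerical and degenerate-input choices

- AR(1) series are generated with stationary N(0,1) marginals (first value
  drawn from the stationary law), so window means are unbiased from the
  first slot.
- Out-of-range ingest rows (outside 40–400 mg/dL) are dropped and counted,
  never clamped — dropped rows are auditable. The generator, by contrast,
  clamps: a sensor would report the rail value.
- Duplicate (user, timestamp) rows collapse to the first occurrence after
  sorting; the count is reported.
- Metrics on an empty window restriction are a per-user skip (such users
  have already failed density filters), not an error; `pct_in_band` and
  `compute_cv` on degenerate vectors error loudly.
- A paired cohort with zero change variance keeps its descriptive summary
  and reports an NA test rather than failing the run.
- SEM for a one-user week is reported as 0 with a warning rather than
  dropping the point.
- All generator randomness flows from a single integer seed; the streamed
  (user-at-a-time) and materialized generation paths consume the RNG in
  the same order and agree exactly.

## Problem sizes

The test suite exercises the full pipeline at 2,000 users over the two
canonical 8-week windows (≈50 M readings, processed user-at-a-time) for
parameter recovery, 200 simulated 30-user cohorts on 1-week windows for
the type-I-error check, and ≥100-fixture oracle-equivalence loops for
every statistic; unit tests run on toy windows of 1–2 weeks. These sizes
were chosen so the whole suite completes in a few minutes on a laptop
while keeping Monte-Carlo error well inside the asserted bands.

## Interface note

The package is function-first: readers for the three CSV schemas, one
function per analysis stage, and `run_pipeline()` as the one-command
driver with staged logging and JSON/CSV artifacts. A shell entry point
would add nothing for the intended audience (R users analyzing tabular
exports), so none is shipped.
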