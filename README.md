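# cgmtrends

Population-scale analysis of real-time continuous glucose monitoring (CGM)
data around a disruptive event — built for biostatisticians and
epidemiologists who want to track glycemic control across a large uploader
population with temporal and geographic resolution, and to test whether
changes in control are associated with local disease burden, income, or
device tenure.

The package implements, end to end:

- **Inclusion filtering.** Users qualify when they started using the device
  on or before Jan 1, 2020, viewed data on the mobile app, uploaded at least
  one value in every month of Jan–Jun 2020, and uploaded ≥200 sensor values
  per day on ≥4 days per week in both observation windows (the density rule
  is relaxable, and "per week" can be read per-calendar-week or as a window
  total). Every exclusion is reported with its reasons.
- **Consensus glycemic metrics** per user per 8-week window: time in range
  (TIR, % of readings in 70–180 mg/dL, endpoints inclusive), time below
  range (<70, level 2 <54 mg/dL), time above range (>180, level 2
  >250 mg/dL), mean glucose, SD, coefficient of variation
  CV = 100·SD/mean, and the glucose management indicator

  GMI (%) = 3.31 + 0.02392 · mean glucose (mg/dL),

  with the consensus goals TIR ≥ 70% and TAR>250 < 5%.
- **Paired pre/post comparison.** Per-user ΔTIR = TIR_post − TIR_pre,
  classified as clinically meaningful when |ΔTIR| ≥ 5 points (inclusive),
  with the dependent t-test for paired samples
  t = mean(Δ)/(SD(Δ)/√n), df = n − 1; plus TIR histograms and weekly
  mean ± SEM trajectory series per county or region.
- **Stratification and ecological correlation.** Pre/post mean TIR with
  normal 95% CIs by zip-level median household income band, CDC
  "Integrated Food Safety Centers of Excellence" region, and device-tenure
  band; and the Pearson correlation, across counties with ≥200 users,
  between log county COVID-19 deaths and the fraction of users with
  meaningful TIR improvement (two-sided p via t = r·√((n−2)/(1−r²))).
- **A calibrated synthetic cohort generator.** Real uploader data are
  proprietary, so the package ships a generative model (lognormal
  within-user glucose with AR(1) 5-minute dependence, between-user spread,
  an income gradient, a county burden coupling, and a step change at the
  stay-at-home date) whose defaults are calibrated to the published
  population statistics (mean TIR ≈ 59% with SD ≈ 20, paired change
  ≈ +2 ± 10 points, mean glucose 173.3 → 170.2 mg/dL). Every downstream
  stage is tested against it, including parameter-recovery and type-I-error
  checks.

## Worked example

A complete run on a 400-user synthetic cohort (generation → filtering →
metrics → paired comparison → stratification → burden correlation):

```r
library(cgmtrends)

cfg <- pipeline_config(
  generator = generator_config(n_users = 400, n_counties = 8, seed = 2020),
  min_users = 25,           # county floor for the burden correlation
  seed = 2020,
  out_dir = file.path(tempdir(), "cgm_demo")
)
res <- run_pipeline(cfg)
#> [generate] 400 users, 8 counties, 10420154 readings
#> [filter] 315 of 400 users included
#> [metrics] pre: 315 users, post: 315 users
#> [compare] mean delta TIR 2.23 points, p = 1.08e-05
#> [stratify] 12 strata across 3 scheme(s)
#> [burden] r = 0.917 over 3 counties

res
#> <pipeline_result: 315/400 users included>
#> <cgm_comparison: 315 paired users>
#>   TIR: 59.8 (19.9)% -> 62.0 (20.6)%, change 2.2 (8.9) points
#>   improved (delta > 0): 56.5%; meaningful +/-5: 36.2% up, 18.7% down
#>   paired t = 4.47, df = 314, p = 1.08e-05
#>   burden correlation r = 0.917 (p = 0.261, 3 counties)
```

Reading the output: 85 of 400 users fail at least one inclusion criterion
(`res$reports` lists which); across the 315 paired users, mean TIR rises
from 59.8% prepandemic to 62.0% intrapandemic, a change of +2.2 points
(SD 8.9) that the paired t-test calls highly non-null; 36.2% of users gain
at least 5 TIR points (clinically meaningful) versus 18.7% who lose as
much; and counties with more COVID-19 deaths have larger shares of
meaningfully improved users (here only 3 counties clear the 25-user demo
floor, so the correlation is illustrative).

Tidy accessors and plots:

```r
glance(res$comparison)   # one-row cohort summary (means, SDs, test)
tidy(res$comparison)     # per-user paired changes with categories
autoplot(res$comparison) # overlaid pre/post TIR distributions

dplyr::filter(res$strata, scheme == "tenure_bands")
#> # A tibble: 4 × 10
#>   scheme       stratum      n tir_pre_mean tir_pre_lo tir_pre_hi tir_post_mean
#>   <chr>        <chr>    <int>        <dbl>      <dbl>      <dbl>         <dbl>
#> 1 tenure_bands 13-24 mo    67         61.4       56.9       65.9          63.6
#> 2 tenure_bands 25-36 mo    76         60.6       56.4       64.7          63.3
#> 3 tenure_bands <13 mo      79         58.8       54.3       63.4          61.7
#> 4 tenure_bands >=37 mo     93         58.7       54.4       63.0          60.1
```

Every artifact (inclusion report, per-window metrics, per-user changes,
histogram, strata, county summaries, `summary.json`) is also written to
`cfg$out_dir`.

Individual stages are plain functions over data frames and can be used on
real data in the same schemas: `read_glucose_csv()`,
`read_user_metadata()`, `read_county_burden()` (NYT county schema),
`filter_cohort()`, `compute_window_metrics()`, `summarize_comparison()`,
`weekly_trajectory()`, `stratify()`, `county_improver_fractions()`,
`burden_correlation()`.

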