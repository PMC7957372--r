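Package: cgmtrends
Title: Population-Scale Continuous Glucose Monitoring Trend Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for population-scale analysis of real-time continuous
    glucose monitoring (CGM) data around a disruptive event. Implements
    data-density inclusion filters, consensus glycemic metrics (time in
    range, time below/above range, glucose management indicator,
    coefficient of variation), paired pre/post cohort comparison with
    clinically-meaningful-change classification, weekly mean trajectory
    series, stratified summaries by county, CDC region, zip-level median
    household income and device tenure, and the ecological correlation
    between county COVID-19 mortality and the prevalence of meaningful
    time-in-range improvement. Ships a calibrated synthetic cohort
    generator emulating the statistical structure of a large uploader
    population so the full pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    ggplot2,
    lubridate,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
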