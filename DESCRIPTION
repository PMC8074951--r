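Package: trackdays
Title: Harmonization and Paired Longitudinal Analysis of Consumer
    Activity-Tracker Daily Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for physical-activity surveillance with daily summaries
    exported from consumer activity-tracker clouds (Apple, Fitbit, Garmin,
    Google Fit, Oura, Polar, Samsung, Withings). Ingests heterogeneous
    per-provider exports into a canonical long format, applies per-provider
    valid-day (wear-time) rules, aggregates valid days into per-participant
    calendar-period means for steps, activity energy expenditure and
    moderate-to-vigorous physical activity, and runs paired two-period
    contrasts (paired t-test or exact Wilcoxon signed-rank, chosen by a
    normality check or per-variable configuration), including a lockdown
    month split into pre/post sub-periods. A synthetic multi-provider
    cohort generator with seasonal structure, nonwear days and injectable
    step/energy deficits makes every stage testable without access to
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
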