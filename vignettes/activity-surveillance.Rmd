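---
title: "Harmonizing consumer activity-tracker data for longitudinal surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing consumer activity-tracker data for longitudinal surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Consumer activity trackers record daily physical activity continuously
and retrospectively, which makes them attractive for epidemiological
surveillance: a cohort recruited *after* an event (such as the March
2020 COVID-19 lockdown) can still contribute months of pre-event data.
Two obstacles stand between a pile of provider exports and an analysis:

* **Heterogeneity.** Each provider cloud exposes a different subset of
  daily variables. Steps is the only variable all eight supported
  providers share; energy expenditure, intensity minutes, sedentary
  time, sleep and nonwear time are patchy. `capabilities()` encodes
  this matrix, and ingest enforces it: a field a provider cannot supply
  is absent in the canonical data, never zero.
* **Wear time.** A day with the tracker in a drawer looks like a day of
  profound inactivity. Daily summaries carry no epoch-level wear
  record, so wear must be inferred from what each provider does supply.

```{r}
library(trackdays)
capabilities("googlefit")
capabilities("fitbit")
```

## Valid days

The target concept is "worn at least 10 hours". Three provider-specific
proxies implement it (`rule_for()`):

| rule | valid iff | default threshold | providers |
|---|---|---|---|
| step floor | steps > threshold | 150 steps | Apple, Fitbit, Google Fit, Oura, Withings |
| wear sum | sleep + sedentary + LPA + MPA + VPA > threshold | 600 min | Garmin, Samsung |
| nonwear cap | nonwear < threshold | 840 min | Polar |

Conventions worth making explicit:

* **Boundaries are strict.** A Fitbit day with exactly 150 steps, a
  Garmin day with exactly 600 wear minutes, and a Polar day with
  exactly 840 nonwear minutes are all invalid. The inclusive reading
  of the step floor ("days with less than 150 steps excluded") is
  available as `step_floor_inclusive = TRUE`; it moves only the
  single boundary value.
* **Missing rule inputs mean invalid, not error.** A wear-sum day with
  any component absent cannot demonstrate wear; it is excluded with
  reason `"insufficient wear evidence"` and logged, because a single
  ragged export should not abort a cohort analysis.
* **Thresholds are configuration**, since the three rules are proxies
  for the same concept and sensitivity analyses may want to tighten
  them.
* The wear-sum rule for Samsung consumes sedentary/LPA/MPA/VPA fields
  that are not part of Samsung's analysis variable set; these are
  treated as rule-only inputs (`rule_fields()`) that may appear in
  exports without becoming analysis variables.

MVPA is derived as MPA + VPA and only where both exist; a provider
without intensity minutes contributes no MVPA days at all, which is why
day counts may differ between variables for the same participant-month.

## Periods and aggregation

Participant-period means are computed over valid days
(`summarize_periods()`). The standard calendar
(`standard_periods()`) comprises whole months March-December in both
years, a March 2020 split at the lockdown date into March 1-12
(pre) and March 13-31 (post), and March-December yearly spans.

Two aggregation decisions were genuinely open:

* **Yearly means are day-weighted**: the March-December mean is the
  mean over all valid days in the span, not the mean of ten monthly
  means. Day-weighting follows directly from "average over valid
  days", and makes the split-month identity exact: the valid-day-
  weighted recombination of the two March sub-period means equals the
  whole-March mean to machine precision (this invariant is tested at
  1e-9 relative error).
* **`min_days` defaults to 1**: any participant with at least one
  valid day in a period enters that period's paired sample. No
  per-month minimum is imposed by default because the analysis design
  this package reproduces states none; epidemiological practice often
  requires 4-10 valid days, so the threshold is configuration.

## Paired comparisons

For two periods, only participants summarized in **both** contribute,
with differences d_i = mean(later) − mean(earlier), so a lockdown
deficit is negative. Two tests are available:

* **Paired t**: one-sample t on d, reported as mean difference with an
  equal-tailed 95% t-interval (delegated to `stats::t.test`).
* **Wilcoxon signed-rank**: zeros are dropped before ranking (the
  classical convention; Pratt's zero-ranking is available via
  `wilcoxon_zero = "pratt"`), ties are midranked, and the two-sided
  p-value is `min(1, 2·min(P(W ≤ w), P(W ≥ w)))` under the exact null
  distribution of the positive-rank sum for effective n ≤ 25 —
  computed by convolution over the 2^n sign assignments, so it remains
  exact under ties — and under a tie-corrected normal approximation
  (no continuity correction; with midranks the support is not an
  integer lattice) above. The location summary is the plain median of
  the raw differences with their quartile range, zeros included,
  matching the "median (IQR)" reporting convention rather than a
  Hodges-Lehmann pseudomedian.

**Test selection.** Visual histogram checks of normality are not
reproducible, so the shipped default hard-codes the reporting layout
such analyses use — paired t for steps and AEE, Wilcoxon for MVPA — and
`test_override = c(<var> = "auto")` switches to a Shapiro-Wilk gate on
the differences at `normality_alpha` (0.05). Degenerate inputs
(zero-variance differences, all-zero differences) yield a flagged
result with `p = NA` rather than an error.

No multiplicity correction is applied by default across the report's
39 cells (13 contrasts × 3 variables), mirroring common practice for
this design; `p_adjust = "holm"` enables one. Report tables round
steps/kcal/minutes to whole units and p to two significant figures; an
unrounded companion file is always written.

## The synthetic cohort

`generate_cohort()` emulates the study conditions the analysis assumes:
113 participants (39 Fitbit, 74 Garmin), daily records for 2019-2020.
Per participant, baseline steps are lognormal (median 8000 steps/day,
geometric SD 1.4); days add a ±15% annual sinusoid peaking July 1 and
Gaussian noise (SD 2500 steps). AEE is 0.04 kcal/step plus N(0, 40)
kcal noise; MVPA is round(max(0, N(35, 20))) minutes split 80/20 into
MPA/VPA; wear components are scaled so their sum lands in 550-1000 min
on worn days. Five percent of days are nonwear (sub-150 steps, high
nonwear minutes, sub-10-h wear sum — so *both* rule families exclude
them, mirroring the use of the step floor as a wear proxy) and 3% of
days are missing entirely. The default lockdown effect injects −800
steps/day and −75 kcal/day over March 13-31 2020 (`inject_effect()`
floors at zero). Variance parameters are package choices of plausible
magnitude — the emulated study reports no variance components — chosen
once as realistic for adult step data.

**What the generator does not emulate:** weekday/weekend structure,
autocorrelated within-person streaks, provider measurement bias,
dropout, or behaviour change other than the injected additive shift.
Passing simulation tests therefore demonstrates that the pipeline's
algebra and inference behave correctly under a plausible data-generating
process, not that any real cohort satisfies these assumptions.

**Matched windows in the simulation studies.** With a ±15% seasonal
amplitude, mid-March and late-March differ by roughly +130 steps/day of
pure seasonal signal — larger than the paired standard error at n = 113.
An unmatched contrast (March 2019 vs March 13-31 2020) therefore mixes
the injected effect with seasonality, exactly the confounding that
month-matched comparison exists to avoid. The package's simulation
properties consequently use calendar-matched windows: type-I error is
evaluated on March 2019 vs March 2020 (null cohorts; rejection rate
within [0.02, 0.09] for both tests), and effect recovery on March 13-31
2019 vs March 13-31 2020, where the seasonal term cancels by
construction (day-of-year offsets are taken against each year's own
July 1, so the leap day cancels too). The recovered mean difference
still sits a few percent above −800 because the step floor censors a
small fraction of post-injection low-step days — a real feature of
step-floor filtering, visible here because the truth is known.

## Numerical and degenerate-input choices

* Dates are time-zone-free calendar dates; a provider-day is taken as
  reported. The ingest window is Jan 1 2019 - Dec 31 2020.
* Exact signed-rank enumeration is used up to effective n = 25
  (`exact_max_n`); the convolution is O(n · Σ2r) and instant there.
* A contrast needs ≥ 2 pairs (`min_pairs`); normality assessment needs
  ≥ 3 differences; both fail loudly below that.
* Missing measurements are never imputed; a recorded zero is a datum
  (and will fail a step floor on its own merits).
* Problem sizes in the shipped tests: full-size cohorts (113 × 731
  days) for the end-to-end properties, 200 null cohorts for test size,
  50 cohorts for effect recovery — sizes chosen to make the binomial
  bands on those rates meaningfully tight.

## Limitations

* Valid-day rules are daily-summary proxies; no epoch-level wear
  algorithm is possible with this data shape.
* The anonymized design supports no covariate adjustment or
  stratification, and the package deliberately offers none.
* Between-provider device bias is not modelled; month-matched paired
  contrasts difference it out only insofar as each participant keeps
  the same device.
* The exact Wilcoxon path conditions on the observed tie pattern, as
  is standard; p-values under heavy ties remain valid but discrete.
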