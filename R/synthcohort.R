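# Synthetic multi-provider cohort ---------------------------------------
#
# Emulates the structure the analysis assumes: ~113 participants (39
# Fitbit, 74 Garmin by default) with daily summaries over 2019-2020,
# lognormal between-participant step baselines, an annual seasonal
# sinusoid peaking July 1, Gaussian day-to-day noise, nonwear days that
# both valid-day rule families exclude, sporadic missing days, and an
# injectable step/AEE deficit over the lockdown window.

#' Synthetic cohort configuration
#'
#' Defaults describe the emulated study conditions: 113 participants (39
#' Fitbit, 74 Garmin), daily records Jan 1 2019 - Dec 31 2020,
#' between-participant baselines lognormal with median 8000 steps/day and
#' geometric SD 1.4, day-to-day noise SD 2500 steps, +/-15% seasonal
#' sinusoid peaking July 1, AEE of 0.04 kcal/step plus N(0, 40 kcal)
#' noise, MVPA of round(max(0, N(35, 20))) min/day, 5% nonwear days, 3%
#' missing days, and a lockdown deficit of -800 steps/day and -75
#' kcal/day over Mar 13-31 2020.
#'
#' @param n_participants Cohort size.
#' @param provider_mix Named integer vector of participants per provider;
#'   must sum to `n_participants`.
#' @param baseline_median,baseline_gsd Median and geometric SD of the
#'   per-participant baseline step level (lognormal).
#' @param daily_sd Day-to-day step noise SD.
#' @param seasonal_amplitude Relative amplitude of the annual sinusoid.
#' @param lockdown_window Two dates (start, end) of the injected deficit.
#' @param delta_steps,delta_aee Injected additive changes (steps/day,
#'   kcal/day) inside `lockdown_window`; set both to 0 for a null cohort.
#' @param aee_per_step,aee_sd AEE model: `aee = aee_per_step * steps +
#'   N(0, aee_sd)` kcal/day.
#' @param mvpa_mean,mvpa_sd MVPA model: `round(max(0, N(mean, sd)))`
#'   min/day.
#' @param vpa_share Fraction of MVPA minutes labeled vigorous.
#' @param nonwear_prob Per-day probability the tracker is essentially
#'   unworn (low steps, high nonwear minutes, low wear-component sum).
#' @param missing_prob Per-day probability the record is absent entirely.
#' @param wear_range Worn-day range (minutes) into which the
#'   sleep+sedentary+LPA+MPA+VPA sum is scaled.
#' @param start,end Collection span.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 113,
                          provider_mix = c(fitbit = 39, garmin = 74),
                          baseline_median = 8000,
                          baseline_gsd = 1.4,
                          daily_sd = 2500,
                          seasonal_amplitude = 0.15,
                          lockdown_window = c("2020-03-13", "2020-03-31"),
                          delta_steps = -800,
                          delta_aee = -75,
                          aee_per_step = 0.04,
                          aee_sd = 40,
                          mvpa_mean = 35,
                          mvpa_sd = 20,
                          vpa_share = 0.2,
                          nonwear_prob = 0.05,
                          missing_prob = 0.03,
                          wear_range = c(550, 1000),
                          start = "2019-01-01",
                          end = "2020-12-31") {
  cfg <- list(
    n_participants = as.integer(n_participants),
    provider_mix = provider_mix,
    baseline_median = baseline_median, baseline_gsd = baseline_gsd,
    daily_sd = daily_sd, seasonal_amplitude = seasonal_amplitude,
    lockdown_window = as.Date(lockdown_window),
    delta_steps = delta_steps, delta_aee = delta_aee,
    aee_per_step = aee_per_step, aee_sd = aee_sd,
    mvpa_mean = mvpa_mean, mvpa_sd = mvpa_sd, vpa_share = vpa_share,
    nonwear_prob = nonwear_prob, missing_prob = missing_prob,
    wear_range = wear_range,
    start = as.Date(start), end = as.Date(end)
  )
  if (sum(cfg$provider_mix) != cfg$n_participants) {
    stop("provider_mix must sum to n_participants", call. = FALSE)
  }
  if (is.null(names(cfg$provider_mix)) ||
      !all(names(cfg$provider_mix) %in% providers())) {
    stop("provider_mix must be named with known providers", call. = FALSE)
  }
  for (p in c("nonwear_prob", "missing_prob", "vpa_share")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(p, " must lie in [0, 1]", call. = FALSE)
    }
  }
  for (p in c("daily_sd", "aee_sd", "mvpa_sd", "baseline_gsd")) {
    if (cfg[[p]] < 0) stop(p, " must be >= 0", call. = FALSE)
  }
  if (cfg$start < .collection_start || cfg$end > .collection_end ||
      cfg$end < cfg$start) {
    stop("span must lie within 2019-01-01..2020-12-31", call. = FALSE)
  }
  if (cfg$lockdown_window[1] < cfg$start ||
      cfg$lockdown_window[2] > cfg$end) {
    stop("lockdown_window must lie within the collection span",
         call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

# Annual sinusoid as a relative factor; day-of-year offsets are taken
# against the same year's July 1 so matched calendar windows in 2019 and
# 2020 get identical factors despite the leap day.
seasonal_factor <- function(dates, amplitude) {
  doy <- as.integer(format(dates, "%j"))
  jul1 <- as.integer(format(as.Date(paste0(format(dates, "%Y"), "-07-01")),
                            "%j"))
  1 + amplitude * cos(2 * pi * (doy - jul1) / 365.25)
}

#' Generate a synthetic cohort
#'
#' Deterministic given `seed`: the same seed and configuration always
#' produce the identical dataset. Records carry only the fields in each
#' provider's capability set plus its valid-day rule inputs; everything
#' else is absent. Nonwear days combine sub-150 step counts, high
#' nonwear minutes and a sub-threshold wear sum, so every rule family
#' excludes them. The configured lockdown deficit is applied via
#' [inject_effect()] (zero deltas leave the cohort null).
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (mandatory for reproducibility).
#' @return Canonical daily-record tibble.
#' @export
#' @examples
#' \dontrun{
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' }
generate_cohort <- function(config = cohort_config(), seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  n <- config$n_participants
  ids <- sprintf("S%03d", seq_len(n))
  provider <- rep(names(config$provider_mix), config$provider_mix)
  baseline <- stats::rlnorm(n, meanlog = log(config$baseline_median),
                            sdlog = log(config$baseline_gsd))
  ree <- stats::rnorm(n, 1600, 150)

  dates <- seq(config$start, config$end, by = "day")
  nd <- length(dates)
  df <- tibble::tibble(
    participant_id = rep(ids, each = nd),
    provider = rep(provider, each = nd),
    date = rep(dates, times = n),
    baseline = rep(baseline, each = nd),
    ree0 = rep(ree, each = nd)
  )
  m <- nrow(df)
  season <- seasonal_factor(df$date, config$seasonal_amplitude)
  worn <- stats::runif(m) >= config$nonwear_prob
  missing <- stats::runif(m) < config$missing_prob

  steps <- pmax(0, round(df$baseline * season +
                           stats::rnorm(m, 0, config$daily_sd)))
  steps[!worn] <- floor(stats::runif(sum(!worn), 0, 150))

  mvpa <- round(pmax(0, stats::rnorm(m, config$mvpa_mean, config$mvpa_sd)))
  mvpa[!worn] <- 0
  vpa <- round(config$vpa_share * mvpa)
  mpa <- mvpa - vpa

  sleep <- pmax(60, stats::rnorm(m, 430, 45))
  sedentary <- pmax(0, stats::rnorm(m, 290, 80))
  lpa <- pmax(0, stats::rnorm(m, 150, 50))
  # Scale the non-MVPA wear components so the five-component sum lands in
  # wear_range on worn days and well below the 10-h threshold on nonwear
  # days.
  target <- pmin(pmax(sleep + sedentary + lpa + mvpa,
                      config$wear_range[1]), config$wear_range[2])
  target[!worn] <- stats::runif(sum(!worn), 120, 500)
  scale <- pmax(0, (target - mvpa)) / (sleep + sedentary + lpa)
  sleep <- round(sleep * scale, 1)
  sedentary <- round(sedentary * scale, 1)
  lpa <- round(lpa * scale, 1)
  total_wear <- sleep + sedentary + lpa + mvpa

  nonwear <- numeric(m)
  nonwear[worn] <- round(stats::runif(sum(worn), 0,
                                      pmin(820, 1440 - total_wear[worn])), 1)
  nonwear[!worn] <- round(stats::runif(sum(!worn), 850, 1300), 1)

  aee <- pmax(0, round(config$aee_per_step * steps +
                         stats::rnorm(m, 0, config$aee_sd), 1))
  tee <- round(df$ree0 + aee, 1)
  ree0 <- round(df$ree0, 1)

  rec <- tibble::tibble(
    participant_id = df$participant_id,
    provider = df$provider,
    date = df$date,
    steps = steps, tee = tee, aee = aee, ree = ree0,
    lpa = lpa, mpa = mpa, vpa = vpa,
    sedentary = sedentary, sleep = sleep, nonwear = nonwear
  )

  # Blank fields outside each provider's capability + rule-input set.
  for (prov in unique(rec$provider)) {
    allowed <- union(capabilities(prov), rule_fields(prov))
    drop <- setdiff(variable_kinds(), allowed)
    if (length(drop)) {
      rec[rec$provider == prov, drop] <- NA_real_
    }
  }
  rec <- rec[!missing, , drop = FALSE]

  if (config$delta_steps != 0 || config$delta_aee != 0) {
    rec <- inject_effect(rec, config$lockdown_window,
                         config$delta_steps, config$delta_aee)
  }
  rec
}

#' Inject an additive activity change into a date window
#'
#' Adds `delta_steps` to steps (floored at 0) and `delta_aee` to AEE
#' (floored at 0) for every record whose date falls inside the closed
#' window; all other days and all other fields are untouched.
#'
#' @param records Canonical daily-record tibble.
#' @param window Two dates (start, end).
#' @param delta_steps,delta_aee Additive shifts.
#' @return The modified tibble.
#' @export
inject_effect <- function(records, window, delta_steps, delta_aee) {
  window <- as.Date(window)
  stopifnot(length(window) == 2L)
  if (window[2] < window[1]) return(records)
  hit <- records$date >= window[1] & records$date <= window[2]
  records$steps[hit] <- pmax(0, records$steps[hit] + delta_steps)
  records$aee[hit] <- pmax(0, records$aee[hit] + delta_aee)
  records
}
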