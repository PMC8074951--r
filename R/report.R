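# Pipeline driver and report outputs ------------------------------------

#' Monthly cross-participant series for plotting
#'
#' From participant-period summaries, computes per period either the
#' cross-participant mean with SD (steps, AEE) or the median with IQR
#' (MVPA) of the participants' per-day means — the series behind the
#' monthly bar plots.
#'
#' @param summaries Output of [standard_summaries()].
#' @param variable `"steps"`, `"aee"` or `"mvpa"`.
#' @param stat `"mean_sd"` or `"median_iqr"`; defaults to `"median_iqr"`
#'   for MVPA and `"mean_sd"` otherwise.
#' @return Tibble: `period_label`, `year`, `n`, `center`, `lo`, `hi`
#'   (center +/- SD, or quartiles), ordered by period start date.
#' @export
monthly_series <- function(summaries, variable,
                           stat = if (variable == "mvpa") "median_iqr"
                                  else "mean_sd") {
  stat <- match.arg(stat, c("mean_sd", "median_iqr"))
  s <- summaries[summaries$variable == variable, ]
  monthly <- dplyr::bind_rows(standard_periods("monthly_2019"),
                              standard_periods("monthly_2020_split_march"))
  s <- s[paste(s$period_label, s$year) %in%
           paste(monthly$label, monthly$year), ]
  grp <- dplyr::group_by(s, .data$period_label, .data$year)
  out <- if (stat == "mean_sd") {
    dplyr::summarise(grp, n = dplyr::n(),
                     center = mean(.data$mean_per_day),
                     spread = stats::sd(.data$mean_per_day),
                     lo = center - spread,
                     hi = center + spread,
                     .groups = "drop")[, c("period_label", "year", "n",
                                           "center", "lo", "hi")]
  } else {
    dplyr::summarise(grp, n = dplyr::n(),
                     center = stats::median(.data$mean_per_day),
                     lo = stats::quantile(.data$mean_per_day, 0.25,
                                          names = FALSE),
                     hi = stats::quantile(.data$mean_per_day, 0.75,
                                          names = FALSE),
                     .groups = "drop")
  }
  ord <- monthly[match(paste(out$period_label, out$year),
                       paste(monthly$label, monthly$year)), "start",
                 drop = TRUE]
  out[order(ord), ]
}

#' Bar plot of a monthly series
#'
#' Cosmetic companion to [monthly_series()] (tests and reports rely on
#' the data files, not the rendering). Requires ggplot2.
#'
#' @param series Output of [monthly_series()].
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_monthly_series <- function(series, ylab = "per day") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  series$period <- factor(paste(series$period_label, series$year),
                          levels = paste(series$period_label, series$year))
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$period, y = .data$center)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.3) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 60, hjust = 1))
}

# Report printing convention: steps/kcal/minutes to whole units, p to 2
# significant figures (3 when p < 0.01 would lose all precision).
round_report <- function(report) {
  report$estimate <- round(report$estimate)
  report$dispersion_lo <- round(report$dispersion_lo)
  report$dispersion_hi <- round(report$dispersion_hi)
  report$p <- signif(report$p, 2)
  report
}

#' Simulate a synthetic cohort to a canonical CSV
#'
#' @param out Output CSV path.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return The cohort tibble, invisibly.
#' @export
cmd_simulate <- function(out, config = cohort_config(), seed) {
  cohort <- generate_cohort(config, seed = seed)
  if (nrow(cohort) == 0L) {
    warning("simulated cohort is empty", call. = FALSE)
  }
  write_canonical(cohort, out)
  message(sprintf("simulate: wrote %d records for %d participants to %s",
                  nrow(cohort), length(unique(cohort$participant_id)),
                  out))
  invisible(cohort)
}

#' Run the full analysis pipeline on a canonical CSV
#'
#' Reads the canonical file, applies valid-day filtering, builds
#' participant-period summaries, runs the 13 x 3 comparison report and
#' writes all outputs to `outdir`:
#'
#' * `report.csv` — rounded comparison table (report printing
#'   convention), `report_full.csv` — the same rows unrounded;
#' * `monthly_steps.csv`, `monthly_aee.csv` (mean +/- SD) and
#'   `monthly_mvpa.csv` (median, IQR) plot-data series;
#' * `summaries.csv` — participant-period means;
#' * `exclusions.csv` — reason-coded excluded days.
#'
#' Counts at each stage (read, valid, excluded) are logged with
#' `message()`; every input row ends up either in the analysis or in the
#' exclusion log.
#'
#' @param input Canonical CSV path.
#' @param outdir Output directory (created if needed).
#' @param config A [trackdays_config()].
#' @return The unrounded report tibble, invisibly.
#' @export
cmd_analyze <- function(input, outdir, config = trackdays_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  records <- read_canonical(input)
  message(sprintf("analyze: read %d records / %d participants",
                  nrow(records), length(unique(records$participant_id))))
  fv <- filter_valid(records, config)
  message(sprintf("analyze: %d valid days, %d excluded",
                  fv$n_valid, fv$n_excluded))
  write_exclusion_log(fv$exclusions, file.path(outdir, "exclusions.csv"))
  summaries <- standard_summaries(fv$valid_days, config)
  write_summaries(summaries, file.path(outdir, "summaries.csv"))
  report <- withCallingHandlers(
    full_report(summaries, config),
    warning = function(w) {
      message("analyze: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (nrow(report) == 0L) {
    warning("no comparisons could be formed", call. = FALSE)
  }
  readr::write_csv(round_report(report),
                   file.path(outdir, "report.csv"), na = "")
  readr::write_csv(report, file.path(outdir, "report_full.csv"), na = "")
  for (v in c("steps", "aee", "mvpa")) {
    readr::write_csv(monthly_series(summaries, v),
                     file.path(outdir, paste0("monthly_", v, ".csv")),
                     na = "")
  }
  message(sprintf("analyze: %d comparison rows written to %s",
                  nrow(report), outdir))
  invisible(report)
}

#' Render the comparison report
#'
#' @param outdir Directory holding `report.csv` from [cmd_analyze()].
#' @param format `"csv"` (returns the tibble) or `"md"` (returns a
#'   markdown table as a character vector).
#' @return See `format`.
#' @export
cmd_report <- function(outdir, format = c("csv", "md")) {
  format <- match.arg(format)
  report <- readr::read_csv(file.path(outdir, "report.csv"),
                            show_col_types = FALSE)
  if (format == "csv") return(report)
  header <- paste(names(report), collapse = " | ")
  sep <- paste(rep("---", ncol(report)), collapse = " | ")
  rows <- apply(report, 1, function(r) paste(r, collapse = " | "))
  c(header, sep, unname(rows))
}
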