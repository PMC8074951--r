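# Per-participant period means ------------------------------------------

#' Per-participant period means over valid days
#'
#' For each participant and period, averages a variable over the valid
#' days inside the period's date intervals. Days on which the variable is
#' absent (e.g. MVPA for a provider without intensity minutes) contribute
#' neither to the mean nor to its day count, so day counts may differ
#' across variables for the same participant-period. Participant-periods
#' with fewer than `min_days` contributing days are omitted (never
#' zero-filled).
#'
#' @param valid_days Harmonized valid-day tibble from [filter_valid()].
#' @param periods Period tibble from [standard_periods()] or [period()].
#' @param variable One of `"steps"`, `"aee"`, `"mvpa"` (any canonical
#'   variable is accepted).
#' @param min_days Minimum contributing valid days (default 1).
#' @return Tibble: `participant_id`, `period_label`, `year`, `variable`,
#'   `mean_per_day`, `n_valid_days`.
#' @export
#' @examples
#' \dontrun{
#' summarize_periods(vd, standard_periods("monthly_2019"), "steps")
#' }
summarize_periods <- function(valid_days, periods, variable,
                              min_days = 1) {
  stopifnot(length(variable) == 1L,
            variable %in% c(variable_kinds(), "mvpa"))
  if (nrow(valid_days) == 0L || nrow(periods) == 0L) {
    return(tibble::tibble(participant_id = character(),
                          period_label = character(), year = integer(),
                          variable = character(), mean_per_day = numeric(),
                          n_valid_days = integer()))
  }
  days <- valid_days[c("participant_id", "date", variable)]
  names(days)[3] <- "value"
  days <- days[!is.na(days$value), ]
  hits <- dplyr::inner_join(
    days, periods,
    by = dplyr::join_by(between(date, start, end)),
    relationship = "many-to-many"
  )
  out <- dplyr::summarise(
    dplyr::group_by(hits, .data$participant_id, .data$label, .data$year),
    mean_per_day = mean(.data$value),
    n_valid_days = dplyr::n(),
    .groups = "drop"
  )
  out <- out[out$n_valid_days >= min_days, ]
  tibble::tibble(
    participant_id = out$participant_id,
    period_label = out$label,
    year = out$year,
    variable = variable,
    mean_per_day = out$mean_per_day,
    n_valid_days = as.integer(out$n_valid_days)
  )
}

#' Summaries for every standard period and analysis variable
#'
#' Convenience wrapper building the full summary table the comparison
#' report consumes: monthly 2019, split-March monthly 2020 and yearly
#' March-December periods, for steps, AEE and MVPA.
#'
#' @inheritParams summarize_periods
#' @param config A [trackdays_config()] (supplies `min_days`).
#' @return Row-bound [summarize_periods()] tibble.
#' @export
standard_summaries <- function(valid_days, config = trackdays_config()) {
  periods <- dplyr::bind_rows(
    standard_periods("monthly_2019"),
    standard_periods("monthly_2020_split_march"),
    standard_periods("yearly_mar_dec")
  )
  dplyr::bind_rows(lapply(c("steps", "aee", "mvpa"), function(v) {
    summarize_periods(valid_days, periods, v, min_days = config$min_days)
  }))
}

#' Write a summaries CSV
#'
#' @param summaries Output of [summarize_periods()] /
#'   [standard_summaries()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  readr::write_csv(summaries, path, na = "", progress = FALSE)
  invisible(path)
}
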