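# Calendar periods ------------------------------------------------------
#
# A period set is a tibble with one row per closed date interval:
#   label (chr), year (int), start (Date), end (Date)
# A period is identified by (label, year); the standard schemes use a
# single interval per period but user-defined periods may span several.

.collection_start <- as.Date("2019-01-01")
.collection_end   <- as.Date("2020-12-31")

#' Define a calendar period
#'
#' @param label Period label, e.g. `"March"` or `"March 13-31"`.
#' @param start,end Closed interval bounds (coerced with [as.Date()]);
#'   vectors of equal length define a multi-interval period.
#' @param year Year tag used to identify the period (defaults to the year
#'   of `start`).
#' @return A one-period tibble with columns `label`, `year`, `start`, `end`.
#' @export
#' @examples
#' period("March", "2019-03-01", "2019-03-31")
period <- function(label, start, end, year = NULL) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (length(start) != length(end)) {
    stop("start and end must have equal length", call. = FALSE)
  }
  if (any(end < start)) stop("end before start", call. = FALSE)
  if (any(start < .collection_start) || any(end > .collection_end)) {
    stop("period outside collection window 2019-01-01..2020-12-31",
         call. = FALSE)
  }
  if (is.null(year)) year <- as.integer(format(start[1], "%Y"))
  out <- tibble::tibble(label = label, year = as.integer(year),
                        start = start, end = end)
  check_period_overlap(out)
  out
}

check_period_overlap <- function(periods) {
  for (key in unique(paste(periods$label, periods$year))) {
    p <- periods[paste(periods$label, periods$year) == key, ]
    if (nrow(p) < 2) next
    p <- p[order(p$start), ]
    if (any(p$start[-1] <= p$end[-nrow(p)])) {
      stop("overlapping intervals within period ", key, call. = FALSE)
    }
  }
  invisible(periods)
}

month_period <- function(month, year) {
  start <- as.Date(sprintf("%d-%02d-01", year, month))
  end <- seq(start, by = "1 month", length.out = 2)[2] - 1
  period(month.name[month], start, end, year = year)
}

#' Standard comparison periods
#'
#' Builds the period sets the monthly/yearly activity comparisons use:
#'
#' * `"monthly_2019"` — whole calendar months March..December 2019.
#' * `"monthly_2020_split_march"` — March 2020 split at the lockdown date
#'   into `"March 1-12"` and `"March 13-31"`, then whole months
#'   April..December 2020.
#' * `"yearly_mar_dec"` — one `"March-December"` span per year.
#'
#' @param scheme One of the three scheme names above.
#' @return A period tibble (see [period()]).
#' @export
#' @examples
#' standard_periods("monthly_2020_split_march")
standard_periods <- function(scheme = c("monthly_2019",
                                        "monthly_2020_split_march",
                                        "yearly_mar_dec")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    monthly_2019 = dplyr::bind_rows(lapply(3:12, month_period, year = 2019)),
    monthly_2020_split_march = dplyr::bind_rows(
      period("March 1-12", "2020-03-01", "2020-03-12"),
      period("March 13-31", "2020-03-13", "2020-03-31"),
      dplyr::bind_rows(lapply(4:12, month_period, year = 2020))
    ),
    yearly_mar_dec = dplyr::bind_rows(
      period("March-December", "2019-03-01", "2019-12-31"),
      period("March-December", "2020-03-01", "2020-12-31")
    )
  )
}
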