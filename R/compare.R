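# Paired two-period contrasts -------------------------------------------

#' Build the paired sample for a two-period contrast
#'
#' Restricts to participants with a summary in both periods and computes
#' within-participant differences with the sign convention "later period
#' minus earlier period" (`period_b - period_a`), so a lockdown deficit
#' appears negative.
#'
#' @param summaries Summary tibble from [summarize_periods()] /
#'   [standard_summaries()].
#' @param variable Variable to contrast (`"steps"`, `"aee"`, `"mvpa"`).
#' @param label_a,year_a,label_b,year_b Period identifiers (label + year
#'   tag) of the earlier (`a`) and later (`b`) period.
#' @param min_pairs Minimum number of paired participants (default 2).
#' @return Tibble: `participant_id`, `mean_a`, `mean_b`, `diff`.
#' @export
build_pairs <- function(summaries, variable, label_a, year_a,
                        label_b, year_b, min_pairs = 2) {
  pick <- function(label, year) {
    s <- summaries[summaries$variable == variable &
                     summaries$period_label == label &
                     summaries$year == year, ]
    tibble::tibble(participant_id = s$participant_id,
                   mean_per_day = s$mean_per_day)
  }
  a <- pick(label_a, year_a)
  b <- pick(label_b, year_b)
  pairs <- dplyr::inner_join(a, b, by = "participant_id",
                             suffix = c("_a", "_b"))
  pairs <- tibble::tibble(participant_id = pairs$participant_id,
                          mean_a = pairs$mean_per_day_a,
                          mean_b = pairs$mean_per_day_b,
                          diff = pairs$mean_per_day_b -
                            pairs$mean_per_day_a)
  if (nrow(pairs) < min_pairs) {
    stop(sprintf("insufficient pairs for %s: %s %d vs %s %d (n=%d)",
                 variable, label_a, year_a, label_b, year_b,
                 nrow(pairs)), call. = FALSE)
  }
  pairs
}

#' Run one paired two-period comparison
#'
#' Builds the paired sample, chooses the test (per-variable override in
#' `config$test_override`, or Shapiro-Wilk on the differences when set to
#' `"auto"`), and reports the estimate with its dispersion: mean
#' difference with 95% CI for the paired t-test, median difference with
#' IQR for the Wilcoxon signed-rank test.
#'
#' @inheritParams build_pairs
#' @param comparison_label Row label for the report (defaults to the
#'   period labels).
#' @param config A [trackdays_config()].
#' @return One-row tibble: `comparison_label`, `variable`, `test`,
#'   `n_pairs`, `estimate`, `dispersion_lo`, `dispersion_hi`, `p`,
#'   `significant`, `degenerate`.
#' @export
run_comparison <- function(summaries, variable, label_a, year_a,
                           label_b, year_b,
                           comparison_label = NULL,
                           config = trackdays_config()) {
  if (is.null(comparison_label)) {
    comparison_label <- sprintf("%s %d vs %s %d", label_a, year_a,
                                label_b, year_b)
  }
  pairs <- build_pairs(summaries, variable, label_a, year_a,
                       label_b, year_b, min_pairs = config$min_pairs)
  d <- pairs$diff
  choice <- config$test_override[[variable]]
  if (is.null(choice) || identical(choice, "auto")) {
    choice <- if (length(d) >= 3 && stats::sd(d) > 0) {
      if (assess_normality(d, config$normality_alpha)) "paired_t"
      else "wilcoxon"
    } else {
      "paired_t"
    }
  }
  if (stats::sd(d) == 0) {
    return(tibble::tibble(
      comparison_label = comparison_label, variable = variable,
      test = choice, n_pairs = nrow(pairs), estimate = mean(d),
      dispersion_lo = NA_real_, dispersion_hi = NA_real_, p = NA_real_,
      significant = NA, degenerate = TRUE))
  }
  if (choice == "paired_t") {
    fit <- paired_t(d)
    est <- fit$estimate; lo <- fit$ci_lo; hi <- fit$ci_hi
  } else {
    fit <- wilcoxon_signed_rank(d, zero_method = config$wilcoxon_zero,
                                exact_max_n = config$exact_max_n)
    est <- fit$estimate; lo <- fit$iqr_lo; hi <- fit$iqr_hi
  }
  tibble::tibble(
    comparison_label = comparison_label, variable = variable,
    test = choice, n_pairs = nrow(pairs), estimate = est,
    dispersion_lo = lo, dispersion_hi = hi, p = fit$p,
    significant = if (is.na(fit$p)) NA else fit$p < config$alpha,
    degenerate = isTRUE(fit$degenerate))
}

# The 13 standard contrasts: yearly Mar-Dec, March 2019 vs the two
# lockdown sub-periods, April..December month-matched, and the
# within-March pre/post contrast.
standard_contrasts <- function() {
  rows <- list(
    list("March-December", "March-December", 2019, "March-December", 2020),
    list("March 1-12", "March", 2019, "March 1-12", 2020),
    list("March 13-31", "March", 2019, "March 13-31", 2020)
  )
  for (m in 4:12) {
    rows <- c(rows, list(list(month.name[m], month.name[m], 2019,
                              month.name[m], 2020)))
  }
  rows <- c(rows, list(list("March 2020: 1-12 vs 13-31",
                            "March 1-12", 2020, "March 13-31", 2020)))
  rows
}

#' Full comparison report
#'
#' Runs all 13 standard contrasts (March-December yearly; March 2019
#' against the pre- and post-lockdown March 2020 sub-periods;
#' April..December month-matched; and March 2020 pre vs post) for steps,
#' AEE and MVPA. Contrasts that cannot be formed (a period absent from
#' the summaries, or too few paired participants) are omitted with a
#' warning rather than failing the report.
#'
#' @param summaries Output of [standard_summaries()].
#' @param config A [trackdays_config()].
#' @return Tibble with up to 13 x 3 rows (see [run_comparison()]).
#' @export
full_report <- function(summaries, config = trackdays_config()) {
  out <- list()
  for (ct in standard_contrasts()) {
    for (v in c("steps", "aee", "mvpa")) {
      row <- tryCatch(
        run_comparison(summaries, v, ct[[2]], ct[[3]], ct[[4]], ct[[5]],
                       comparison_label = ct[[1]], config = config),
        error = function(e) {
          warning(sprintf("omitting %s / %s: %s", ct[[1]], v,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      out[[length(out) + 1L]] <- row
    }
  }
  report <- dplyr::bind_rows(out)
  if (nrow(report) == 0L) {
    report <- tibble::tibble(
      comparison_label = character(), variable = character(),
      test = character(), n_pairs = integer(), estimate = numeric(),
      dispersion_lo = numeric(), dispersion_hi = numeric(),
      p = numeric(), significant = logical(), degenerate = logical())
  }
  if (nrow(report) && config$p_adjust == "holm") {
    report$p_adjusted <- stats::p.adjust(report$p, method = "holm")
    report$significant <- ifelse(is.na(report$p_adjusted), NA,
                                 report$p_adjusted < config$alpha)
  }
  report
}
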