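# Valid-day classification ----------------------------------------------
#
# Daily summaries carry no epoch-level wear record, so each provider's
# rule is a proxy for "worn at least 10 hours": a step floor, a
# wear-component sum, or a nonwear cap, as exposed by that provider.

.rule_kind <- list(
  apple = "step_floor", fitbit = "step_floor", googlefit = "step_floor",
  oura = "step_floor", withings = "step_floor",
  garmin = "wear_sum", samsung = "wear_sum",
  polar = "nonwear_cap"
)

#' Construct a valid-day rule
#'
#' @param kind `"step_floor"` (valid iff `steps > threshold`),
#'   `"wear_sum"` (valid iff `sleep + sedentary + lpa + mpa + vpa >
#'   threshold` minutes) or `"nonwear_cap"` (valid iff `nonwear <
#'   threshold` minutes).
#' @param threshold Steps for `step_floor`, minutes otherwise.
#' @param inclusive For `step_floor` only: treat exactly `threshold`
#'   steps as valid (`steps >= threshold`).
#' @return A `valid_day_rule` list.
#' @export
valid_day_rule <- function(kind = c("step_floor", "wear_sum", "nonwear_cap"),
                           threshold, inclusive = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  structure(list(kind = kind, threshold = threshold,
                 inclusive = isTRUE(inclusive)),
            class = "valid_day_rule")
}

#' The valid-day rule a provider uses
#'
#' Apple, Fitbit, Google Fit, Oura and Withings use a 150-step floor;
#' Garmin and Samsung a 10-hour wear-component sum; Polar a 14-hour
#' nonwear cap. Thresholds come from `config`.
#'
#' @param provider One of [providers()].
#' @param config A [trackdays_config()].
#' @return A [valid_day_rule()].
#' @export
#' @examples
#' rule_for("polar")
rule_for <- function(provider, config = trackdays_config()) {
  assert_provider(provider)
  switch(.rule_kind[[provider]],
    step_floor = valid_day_rule("step_floor", config$step_floor,
                                inclusive = config$step_floor_inclusive),
    wear_sum = valid_day_rule("wear_sum", config$wear_min),
    nonwear_cap = valid_day_rule("nonwear_cap", config$nonwear_max)
  )
}

#' Derive moderate-to-vigorous physical activity
#'
#' MVPA is the sum of moderate and vigorous activity minutes; it is only
#' derivable on days where both components are present (absent components
#' propagate, so providers without intensity minutes never get an MVPA
#' value).
#'
#' @param records A canonical daily-record tibble (columns `mpa`, `vpa`).
#' @return Numeric vector of MVPA minutes, `NA` where underivable.
#' @export
compute_mvpa <- function(records) {
  records$mpa + records$vpa
}

#' Classify days against a valid-day rule
#'
#' Vectorized over the rows of `records`. Days whose rule inputs are
#' missing are invalid with reason `"insufficient wear evidence"` —
#' wear cannot be demonstrated — rather than an error.
#'
#' @param records Canonical daily-record tibble.
#' @param rule A [valid_day_rule()].
#' @return List with logical `valid` and character `reason` (`NA` for
#'   valid days).
#' @export
is_valid_day <- function(records, rule) {
  stopifnot(inherits(rule, "valid_day_rule"))
  n <- nrow(records)
  thr <- rule$threshold
  switch(rule$kind,
    step_floor = {
      s <- records$steps
      ok <- !is.na(s) & (if (rule$inclusive) s >= thr else s > thr)
      reason <- ifelse(is.na(s), "insufficient wear evidence",
                       sprintf("steps at or below floor (%g)", thr))
    },
    wear_sum = {
      worn <- records$sleep + records$sedentary + records$lpa +
        records$mpa + records$vpa
      ok <- !is.na(worn) & worn > thr
      reason <- ifelse(is.na(worn), "insufficient wear evidence",
                       sprintf("wear sum at or below %g min", thr))
    },
    nonwear_cap = {
      nw <- records$nonwear
      ok <- !is.na(nw) & nw < thr
      reason <- ifelse(is.na(nw), "insufficient wear evidence",
                       sprintf("nonwear at or above %g min", thr))
    }
  )
  reason[ok] <- NA_character_
  list(valid = ok, reason = reason)
}

#' Split a dataset into valid and excluded days
#'
#' Each day is judged by its own provider's rule. Valid days gain a
#' derived `mvpa` column and a `rule` tag; excluded days go to a
#' reason-coded exclusion log.
#'
#' @param records Canonical daily-record tibble.
#' @param config A [trackdays_config()].
#' @return List: `valid_days` (harmonized tibble), `n_valid`,
#'   `n_excluded`, `exclusions` (tibble `participant_id`, `date`,
#'   `provider`, `rule`, `reason`).
#' @export
filter_valid <- function(records, config = trackdays_config()) {
  n <- nrow(records)
  valid <- logical(n)
  reason <- character(n)
  rule_tag <- character(n)
  for (prov in unique(records$provider)) {
    idx <- which(records$provider == prov)
    rule <- rule_for(prov, config)
    res <- is_valid_day(records[idx, ], rule)
    valid[idx] <- res$valid
    reason[idx] <- res$reason
    rule_tag[idx] <- rule$kind
  }
  out <- records
  out$mvpa <- if (n) compute_mvpa(records) else numeric(0)
  out$rule <- rule_tag
  valid_days <- out[valid, , drop = FALSE]
  excl <- records[!valid, c("participant_id", "date", "provider"),
                  drop = FALSE]
  excl$rule <- rule_tag[!valid]
  excl$reason <- reason[!valid]
  list(valid_days = tibble::as_tibble(valid_days),
       n_valid = sum(valid),
       n_excluded = n - sum(valid),
       exclusions = tibble::as_tibble(excl))
}

#' Write the exclusion log
#'
#' @param exclusions The `exclusions` tibble from [filter_valid()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(exclusions, path) {
  readr::write_csv(exclusions, path, na = "")
  invisible(path)
}
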