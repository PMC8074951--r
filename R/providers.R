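#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

#' Supported activity-tracker providers
#'
#' The eight provider ecosystems whose daily summaries the package can
#' harmonize. Trackers that store data in the Google Fit or Apple open
#' health clouds are covered by the `googlefit` / `apple` entries.
#'
#' @return Character vector of the eight provider names.
#' @export
#' @examples
#' providers()
providers <- function() {
  c("apple", "fitbit", "garmin", "googlefit", "oura", "polar",
    "samsung", "withings")
}

#' Daily variables known to the harmonization layer
#'
#' Units: `steps` is a count/day; `tee`, `aee`, `ree` are kcal/day (total,
#' activity and resting energy expenditure); `lpa`, `mpa`, `vpa` (light /
#' moderate / vigorous physical activity), `sedentary`, `sleep` and
#' `nonwear` are minutes/day.
#'
#' @return Character vector of the ten variable names.
#' @export
variable_kinds <- function() {
  c("steps", "tee", "aee", "ree", "lpa", "mpa", "vpa",
    "sedentary", "sleep", "nonwear")
}

# Which daily variables each provider's cloud exposes. Steps is the only
# variable available from every provider.
.capability_matrix <- list(
  apple     = c("steps", "aee", "ree", "sleep"),
  fitbit    = c("steps", "tee", "aee", "lpa", "mpa", "vpa", "sleep"),
  garmin    = c("steps", "tee", "aee", "mpa", "vpa"),
  googlefit = c("steps", "tee"),
  oura      = c("steps", "tee", "aee", "sedentary", "lpa", "mpa", "vpa",
                "nonwear"),
  polar     = c("steps", "tee", "aee", "sedentary", "lpa", "mpa", "vpa",
                "sleep"),
  samsung   = c("steps", "aee", "sleep"),
  withings  = c("steps", "tee", "aee", "lpa", "mpa", "vpa", "sleep")
)

assert_provider <- function(provider) {
  if (length(provider) != 1L || !is.character(provider) ||
      !provider %in% providers()) {
    stop("unknown provider: ", paste(provider, collapse = ", "),
         call. = FALSE)
  }
  invisible(provider)
}

#' Variables a provider supplies
#'
#' Returns the set of analysis variables a provider's cloud exposes.
#' Capability sets ship with the package but can be overridden (provider
#' APIs evolve) by passing a named list of character vectors.
#'
#' @param provider One of [providers()].
#' @param overrides Optional named list `provider -> character vector of`
#'   [variable_kinds()] replacing the shipped set for that provider.
#' @return Character vector of variable names; always contains `"steps"`.
#' @export
#' @examples
#' capabilities("googlefit")
#' capabilities("apple")
capabilities <- function(provider, overrides = NULL) {
  assert_provider(provider)
  caps <- .capability_matrix[[provider]]
  if (!is.null(overrides) && provider %in% names(overrides)) {
    caps <- overrides[[provider]]
    bad <- setdiff(caps, variable_kinds())
    if (length(bad)) {
      stop("unknown variable in capability override: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!"steps" %in% caps) {
      stop("every provider must supply steps", call. = FALSE)
    }
  }
  caps
}

#' Variables consumed by a provider's valid-day rule
#'
#' Some valid-day rules read fields that are not part of the provider's
#' analysis variable set (e.g. the wear-component sum for Garmin and
#' Samsung). Such fields may be present in exports as rule inputs without
#' being analysis variables.
#'
#' @param provider One of [providers()].
#' @return Character vector of variable names the rule inspects.
#' @export
rule_fields <- function(provider) {
  assert_provider(provider)
  switch(.rule_kind[[provider]],
    step_floor  = "steps",
    wear_sum    = c("sleep", "sedentary", "lpa", "mpa", "vpa"),
    nonwear_cap = "nonwear"
  )
}
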