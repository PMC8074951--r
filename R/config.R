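# Pipeline configuration -------------------------------------------------

#' Default analysis configuration
#'
#' Returns the configuration list consumed by the valid-day, aggregation
#' and comparison stages. Any element can be overridden by name; unknown
#' names are rejected.
#'
#' Valid-day options:
#' * `step_floor` (150 steps) — step-count floor for step-floor providers.
#' * `step_floor_inclusive` (`FALSE`) — if `TRUE`, a day with exactly
#'   `step_floor` steps counts as valid (the "less than 150 excluded"
#'   reading); default is the strict `steps > floor` convention.
#' * `wear_min` (600 min = 10 h) — wear-component sum threshold (strict
#'   `>`).
#' * `nonwear_max` (840 min = 14 h) — nonwear cap (strict `<`).
#'
#' Aggregation: `min_days` (1) — minimum valid days carrying a variable
#' for a participant-period mean to be emitted.
#'
#' Comparison:
#' * `alpha` (0.05) — two-sided significance level.
#' * `normality_alpha` (0.05) — Shapiro-Wilk level used when a test is
#'   chosen automatically.
#' * `test_override` — named character vector forcing a test per variable;
#'   the shipped default uses the paired t-test for `steps` and `aee` and
#'   the Wilcoxon signed-rank test for `mvpa` (set an entry to `"auto"`
#'   to select by normality of the paired differences instead).
#' * `wilcoxon_zero` (`"drop"`) — zero-difference handling, `"drop"`
#'   (classical) or `"pratt"`.
#' * `exact_max_n` (25) — largest effective n for which the exact
#'   signed-rank null distribution is used; above it a tie-corrected
#'   normal approximation applies.
#' * `min_pairs` (2) — minimum paired participants for a contrast.
#' * `p_adjust` (`"none"`) — optional `"holm"` correction across the
#'   report's contrasts.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list with class `"trackdays_config"`.
#' @export
#' @examples
#' cfg <- trackdays_config(min_days = 4)
#' cfg$min_days
trackdays_config <- function(...) {
  cfg <- list(
    step_floor = 150,
    step_floor_inclusive = FALSE,
    wear_min = 600,
    nonwear_max = 840,
    min_days = 1,
    alpha = 0.05,
    normality_alpha = 0.05,
    test_override = c(steps = "paired_t", aee = "paired_t",
                      mvpa = "wilcoxon"),
    wilcoxon_zero = "drop",
    exact_max_n = 25,
    min_pairs = 2,
    p_adjust = "none",
    capability_overrides = NULL
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("config overrides must be named", call. = FALSE)
    }
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown config option(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$step_floor >= 0, cfg$wear_min >= 0, cfg$nonwear_max >= 0,
    cfg$min_days >= 1,
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$normality_alpha > 0, cfg$normality_alpha < 1,
    cfg$exact_max_n >= 0, cfg$min_pairs >= 2
  )
  if (!cfg$wilcoxon_zero %in% c("drop", "pratt")) {
    stop("wilcoxon_zero must be 'drop' or 'pratt'", call. = FALSE)
  }
  if (!cfg$p_adjust %in% c("none", "holm")) {
    stop("p_adjust must be 'none' or 'holm'", call. = FALSE)
  }
  ok <- c("paired_t", "wilcoxon", "auto")
  if (length(cfg$test_override) &&
      !all(cfg$test_override %in% ok)) {
    stop("test_override entries must be one of: ",
         paste(ok, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "trackdays_config")
}

#' Read / write a configuration as YAML
#'
#' A run's configuration plus its seed reproduce its outputs exactly, so
#' configurations are fully serializable.
#'
#' @param path File path.
#' @param cfg A [trackdays_config()] list.
#' @return `read_config()` returns a `trackdays_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$test_override)) {
    raw$test_override <- unlist(raw$test_override)
  }
  do.call(trackdays_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$test_override <- as.list(out$test_override)
  yaml::write_yaml(out, path)
  invisible(path)
}
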