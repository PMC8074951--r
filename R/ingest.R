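# Canonical daily-record I/O --------------------------------------------
#
# Canonical long format: one participant-day per row, UTF-8 CSV with a
# mandatory header. Empty cells are absent measurements (never zero).

.canonical_csv_cols <- c(
  participant_id = "participant_id", provider = "provider", date = "date",
  steps = "steps", tee = "tee_kcal", aee = "aee_kcal", ree = "ree_kcal",
  lpa = "lpa_min", mpa = "mpa_min", vpa = "vpa_min",
  sedentary = "sedentary_min", sleep = "sleep_min", nonwear = "nonwear_min"
)

.minute_vars <- c("lpa", "mpa", "vpa", "sedentary", "sleep", "nonwear")

empty_canonical <- function() {
  tibble::tibble(
    participant_id = character(), provider = character(),
    date = as.Date(character()),
    steps = numeric(), tee = numeric(), aee = numeric(), ree = numeric(),
    lpa = numeric(), mpa = numeric(), vpa = numeric(),
    sedentary = numeric(), sleep = numeric(), nonwear = numeric()
  )
}

# Shared validation for every ingest path. Errors carry 1-based data row
# numbers (header excluded) so a rejected export can be fixed.
validate_canonical <- function(records, source = "<data>") {
  rowmsg <- function(rows, msg) {
    stop(sprintf("%s: row %s %s", source,
                 paste(utils::head(rows, 5), collapse = ","), msg),
         call. = FALSE)
  }
  if (any(is.na(records$participant_id) | records$participant_id == "")) {
    rowmsg(which(is.na(records$participant_id) |
                   records$participant_id == ""), "missing participant_id")
  }
  bad <- which(!records$provider %in% providers())
  if (length(bad)) rowmsg(bad, paste("unknown provider",
                                     records$provider[bad[1]]))
  if (any(is.na(records$date))) rowmsg(which(is.na(records$date)),
                                       "unparseable date")
  out <- which(records$date < .collection_start |
                 records$date > .collection_end)
  if (length(out)) rowmsg(out, "date outside collection window")
  dup <- which(duplicated(records[c("participant_id", "date")]))
  if (length(dup)) rowmsg(dup, "duplicate (participant_id, date)")
  for (v in setdiff(variable_kinds(), "steps")) {
    neg <- which(records[[v]] < 0)
    if (length(neg)) rowmsg(neg, paste("negative", v))
  }
  neg <- which(records$steps < 0)
  if (length(neg)) rowmsg(neg, "negative steps")
  for (v in .minute_vars) {
    over <- which(records[[v]] > 1440)
    if (length(over)) rowmsg(over, paste(v, "exceeds 1440 min/day"))
  }
  records
}

#' Read a canonical daily-record CSV
#'
#' Columns: `participant_id`, `provider`, `date` (ISO-8601), `steps`,
#' `tee_kcal`, `aee_kcal`, `ree_kcal`, `lpa_min`, `mpa_min`, `vpa_min`,
#' `sedentary_min`, `sleep_min`, `nonwear_min`. Empty cells become absent
#' (`NA`) fields. Rows are rejected (with their row number) when the
#' header is malformed, a value is non-numeric or negative, a minutes
#' field exceeds 1440, the date falls outside the Jan 1 2019 - Dec 31
#' 2020 collection window, or a (participant, date) pair repeats.
#'
#' @param path CSV file path.
#' @return A tibble of daily records (internal variable names, `date` as
#'   `Date`), with a `provenance` attribute recording the source file and
#'   read time.
#' @export
read_canonical <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- names(utils::read.csv(path, nrows = 0, check.names = FALSE))
  if (!identical(sort(header), sort(unname(.canonical_csv_cols)))) {
    stop(path, ": malformed header; expected columns ",
         paste(.canonical_csv_cols, collapse = ", "), call. = FALSE)
  }
  spec <- readr::cols(
    participant_id = readr::col_character(),
    provider = readr::col_character(),
    date = readr::col_date(format = "%Y-%m-%d"),
    .default = readr::col_double()
  )
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = spec, progress = FALSE,
                    na = c("", "NA"))
  )
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    stop(path, ": row ", probs$row[1] - 1L, " unparseable value in ",
         "column ", probs$col[1], call. = FALSE)
  }
  names(raw) <- names(.canonical_csv_cols)[match(names(raw),
                                                 .canonical_csv_cols)]
  raw <- raw[names(.canonical_csv_cols)]
  raw <- validate_canonical(raw, source = path)
  attr(raw, "provenance") <- list(source = path, read_at = Sys.time())
  raw
}

#' Write a canonical daily-record CSV
#'
#' Inverse of [read_canonical()]: absent fields become empty cells and
#' numeric values are written at full precision, so a write/read
#' round-trip reproduces the dataset exactly.
#'
#' @param records Canonical daily-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_canonical <- function(records, path) {
  out <- records[names(.canonical_csv_cols)]
  names(out) <- unname(.canonical_csv_cols)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Map a provider export onto the canonical format
#'
#' Provider clouds name their daily fields differently; a field-mapping
#' configuration (`provider -> list(external_name = canonical_name)`)
#' translates an export (CSV, or JSON array of objects) into canonical
#' records. Mapped fields outside the provider's capability set and its
#' valid-day rule inputs are dropped with a warning; an export whose
#' mapping yields no `steps` column is rejected.
#'
#' @param path Export file (`.csv` or `.json`).
#' @param provider One of [providers()].
#' @param mapping Named list of per-provider field maps; defaults to the
#'   mapping shipped in `inst/extdata/provider_fields.yaml`.
#' @param config A [trackdays_config()] (capability overrides).
#' @return Canonical daily-record tibble (see [read_canonical()]).
#' @export
map_provider_export <- function(path, provider,
                                mapping = default_field_mapping(),
                                config = trackdays_config()) {
  assert_provider(provider)
  fmap <- mapping[[provider]]
  if (is.null(fmap)) {
    stop("no field mapping configured for provider ", provider,
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE, na = c("", "NA")),
    json = tibble::as_tibble(jsonlite::fromJSON(path)),
    stop("unsupported export format: .", ext, call. = FALSE)
  )
  known <- intersect(names(raw), names(fmap))
  raw <- raw[known]
  names(raw) <- unname(unlist(fmap[known]))
  if (!"steps" %in% names(raw)) {
    stop(path, ": mandatory field steps is unmapped for provider ",
         provider, call. = FALSE)
  }
  for (key in c("participant_id", "date")) {
    if (!key %in% names(raw)) {
      stop(path, ": mapping yields no ", key, " column", call. = FALSE)
    }
  }
  allowed <- union(capabilities(provider, config$capability_overrides),
                   rule_fields(provider))
  extra <- setdiff(names(raw), c("participant_id", "date", allowed))
  if (length(extra)) {
    warning("dropping field(s) outside ", provider, "'s capability set: ",
            paste(extra, collapse = ", "), call. = FALSE)
    raw <- raw[setdiff(names(raw), extra)]
  }
  n <- nrow(raw)
  rec <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    provider = rep(provider, n),
    date = as.Date(as.character(raw$date))
  )
  for (v in variable_kinds()) {
    rec[[v]] <- if (v %in% names(raw)) {
      x <- raw[[v]]
      if (is.character(x) && length(x) && any(!is.na(x) &
            is.na(suppressWarnings(as.numeric(x))))) {
        bad <- which(!is.na(x) & is.na(suppressWarnings(as.numeric(x))))
        stop(path, ": row ", bad[1], " non-numeric value in ", v,
             call. = FALSE)
      }
      suppressWarnings(as.numeric(x))
    } else {
      rep(NA_real_, n)
    }
  }
  rec <- validate_canonical(rec, source = path)
  attr(rec, "provenance") <- list(source = path, read_at = Sys.time())
  rec
}

#' Shipped provider field mapping
#'
#' @return Named list `provider -> list(external_name = canonical_name)`
#'   read from the package's `provider_fields.yaml`.
#' @export
default_field_mapping <- function() {
  yaml::read_yaml(system.file("extdata", "provider_fields.yaml",
                              package = "trackdays", mustWork = TRUE))
}

# Token handling ---------------------------------------------------------

#' Create a participant/token map
#'
#' Holds the link between internal participant ids and provider access
#' tokens. Stored in an environment so that [anonymize()] can destroy it
#' in place.
#'
#' @param participant_id,token Equal-length character vectors.
#' @return A `token_map` environment.
#' @export
token_map <- function(participant_id = character(), token = character()) {
  stopifnot(length(participant_id) == length(token))
  e <- new.env(parent = emptyenv())
  e$pairs <- tibble::tibble(participant_id = participant_id, token = token)
  class(e) <- "token_map"
  e
}

#' Anonymize a dataset
#'
#' Replaces participant identifiers with fresh opaque ids (`P0001`, ...,
#' in order of first appearance) and destroys the token map, severing the
#' link between stored activity data and provider accounts. The
#' id-to-id correspondence is not persisted anywhere; calling twice
#' simply relabels again.
#'
#' @param records Canonical daily-record tibble.
#' @param tokens Optional [token_map()]; emptied in place.
#' @return The relabeled tibble (same rows, same per-day measurements,
#'   same partition of records into participants).
#' @export
anonymize <- function(records, tokens = NULL) {
  ids <- unique(records$participant_id)
  fresh <- sprintf("P%04d", seq_along(ids))
  records$participant_id <- fresh[match(records$participant_id, ids)]
  if (!is.null(tokens)) {
    stopifnot(inherits(tokens, "token_map"))
    tokens$pairs <- tokens$pairs[0, ]
  }
  records
}
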