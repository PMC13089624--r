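#' Validation events
#'
#' Every data-quality finding the pipeline makes — a cell that would not
#' convert, an out-of-range measurement, an unmapped column, an identifier
#' that breaks the program pattern — is recorded as one structured event
#' with a standardized code and full cell provenance, rather than silently
#' dropping or mutating data. Codes prefixed `W_` are warnings (something
#' was substituted, retained-but-suspect, or skipped); codes prefixed `I_`
#' are informational (a recoverable transformation was applied, such as a
#' centimetre-to-metre conversion).
#'
#' @section Event codes:
#' \describe{
#'   \item{W_TYPE_NUM}{numeric conversion failed; numeric sentinel substituted}
#'   \item{W_TYPE_DATE}{no date format matched; date sentinel substituted}
#'   \item{W_RANGE}{value outside clinically plausible bounds; sentinel substituted}
#'   \item{W_CATEGORY}{value not in the allowed set; raw text retained}
#'   \item{W_BP_MALFORMED}{blood-pressure string did not parse; sentinels substituted}
#'   \item{W_ID_PATTERN}{identifier does not match the program pattern}
#'   \item{W_NAME_UNMATCHED}{name not found in the Patient List roster; redacted}
#'   \item{W_UNMAPPED_COLUMN}{header matches no known synonym}
#'   \item{W_DUPLICATE_MAPPING}{two headers map to one canonical variable}
#'   \item{W_NO_HEADER}{no recognizable header row; sheet skipped}
#'   \item{W_MISSING_KEY}{record lacks its entity key; excluded from staging}
#'   \item{I_HBA1C_THRESHOLD}{inequality prefix stripped; threshold flag set}
#'   \item{I_HEIGHT_CONVERTED}{height read as centimetres, divided by 100}
#'   \item{I_DATE_MONTH_PRECISION}{month-only date completed to day 1}
#'   \item{I_DATE_DAYFIRST}{day/month numeric date ambiguous; day-first used}
#' }
#'
#' @name validation-events
NULL

EVENT_CODES <- c(
  "W_TYPE_NUM", "W_TYPE_DATE", "W_RANGE", "W_CATEGORY", "W_BP_MALFORMED",
  "W_ID_PATTERN", "W_NAME_UNMATCHED", "W_UNMAPPED_COLUMN",
  "W_DUPLICATE_MAPPING", "W_NO_HEADER", "W_MISSING_KEY",
  "I_HBA1C_THRESHOLD", "I_HEIGHT_CONVERTED", "I_DATE_MONTH_PRECISION",
  "I_DATE_DAYFIRST"
)

# Internal constructor: a plain named list for speed; events are bound into
# a tibble once per run with events_tibble().
new_event <- function(code, workbook = NA_character_, sheet = NA_character_,
                      row = NA_integer_, column = NA_character_,
                      raw = NA_character_, substituted = NA_character_,
                      clinic = NA_character_, period = NA_character_) {
  stopifnot(code %in% EVENT_CODES)
  list(
    code = code,
    severity = if (startsWith(code, "W_")) "warning" else "info",
    workbook = workbook, sheet = sheet, row = row, column = column,
    raw = raw, substituted = substituted, clinic = clinic, period = period
  )
}

#' Collect validation events into a tibble
#'
#' @param events A list of events as produced internally by the cleaning and
#'   extraction functions (each a named list), possibly empty.
#' @return A tibble with one row per event and columns `code`, `severity`,
#'   `workbook`, `sheet`, `row` (0-based), `column`, `raw`, `substituted`,
#'   `clinic`, `period`.
#' @export
events_tibble <- function(events = list()) {
  cols <- c("code", "severity", "workbook", "sheet", "row", "column",
            "raw", "substituted", "clinic", "period")
  if (length(events) == 0) {
    return(tibble::tibble(
      code = character(), severity = character(), workbook = character(),
      sheet = character(), row = integer(), column = character(),
      raw = character(), substituted = character(), clinic = character(),
      period = character()
    ))
  }
  out <- dplyr::bind_rows(lapply(events, function(e) {
    e$row <- as.integer(e$row)
    tibble::as_tibble(e[cols])
  }))
  out
}

#' Write validation events as JSON Lines
#'
#' One event per line, stable key order, so logs can be streamed, diffed and
#' audited. Writing the same events twice yields identical bytes.
#'
#' @param events A tibble from [events_tibble()] (or a list of events).
#' @param path Output file path (conventionally `events.jsonl`).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  if (!inherits(events, "data.frame")) events <- events_tibble(events)
  lines <- vapply(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE, na = "null",
                     digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON Lines event log
#'
#' Malformed lines are never dropped silently: each one becomes a row with
#' code `PARSE_ERROR` carrying the offending line in `raw`.
#'
#' @param path Path to a `.jsonl` event log.
#' @return A tibble in the [events_tibble()] layout.
#' @export
read_events <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(events_tibble())
  evs <- lapply(lines, function(l) {
    parsed <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(parsed) || is.null(parsed$code)) {
      return(list(code = "PARSE_ERROR", severity = "warning",
                  workbook = NA_character_, sheet = NA_character_,
                  row = NA_integer_, column = NA_character_, raw = l,
                  substituted = NA_character_, clinic = NA_character_,
                  period = NA_character_))
    }
    defaults <- list(code = NA_character_, severity = NA_character_,
                     workbook = NA_character_, sheet = NA_character_,
                     row = NA_integer_, column = NA_character_,
                     raw = NA_character_, substituted = NA_character_,
                     clinic = NA_character_, period = NA_character_)
    for (k in names(defaults)) {
      v <- parsed[[k]]
      if (!is.null(v) && length(v) == 1 && !is.na(v)) defaults[[k]] <- v
    }
    defaults$row <- as.integer(defaults$row)
    defaults
  })
  dplyr::bind_rows(evs)
}
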