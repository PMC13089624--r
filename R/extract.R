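#' Extraction stage
#'
#' Reads anonymized workbooks, finds the data boundaries of every monthly
#' worksheet (decorative title rows above the header, an optional
#' case-insensitive `END` marker row below the data), and maps each raw
#' column header onto the canonical schema through the synonym map. All
#' coordinates are 0-based and spans half-open, consistently in provenance
#' and logs.
#'
#' @name extraction
NULL

# Rows of the data span: from header_row + 1 (1-based) to the first fully
# empty row or END-marker row, exclusive. Returns integer vector (possibly
# empty) of 1-based row indices.
data_span_rows <- function(mat, header_row) {
  nr <- nrow(mat)
  if (header_row >= nr) return(integer(0))
  rows <- integer(0)
  for (r in (header_row + 1):nr) {
    vals <- mat[r, ]
    if (all(is_blank(vals))) break
    first <- vals[which(!is_blank(vals))[1]]
    if (identical(normalize_header(first), "end")) break
    rows <- c(rows, r)
  }
  rows
}

#' Detect the data region of one sheet
#'
#' The header row is the first row in which at least `min_hits` cells
#' normalize onto known synonyms; the data span runs from the next row to
#' the first fully empty row, an `END` marker cell, or the sheet end,
#' whichever comes first.
#'
#' @param mat Character matrix for one sheet (see [read_workbook()]).
#' @param config A [load_config()] object.
#' @param min_hits Minimum synonym hits for a row to count as a header.
#' @return A list with `header_row` (0-based), `data_start`, `data_end`
#'   (0-based half-open span) and `headers` (raw header strings), or `NULL`
#'   when no recognizable header exists.
#' @export
detect_region <- function(mat, config, min_hits = 3) {
  if (is.null(dim(mat)) || nrow(mat) == 0) return(NULL)
  for (r in seq_len(nrow(mat))) {
    hits <- sum(normalize_header(mat[r, ]) %in% names(config$synonyms))
    if (hits >= min_hits) {
      rows <- data_span_rows(mat, r)
      data_start <- r  # 0-based: first row after the 1-based header row r
      data_end <- if (length(rows) == 0) r else max(rows)
      return(list(header_row = r - 1L, data_start = data_start - 0L,
                  data_end = as.integer(data_end),
                  headers = mat[r, ]))
    }
  }
  NULL
}

#' Map raw headers onto canonical variables
#'
#' Each header is matched via [normalize_header()] against the synonym map.
#' Unmatched headers are marked unmapped and logged once per sheet and
#' header (`W_UNMAPPED_COLUMN`); when two raw headers resolve to the same
#' canonical variable the second occurrence is ignored with a
#' `W_DUPLICATE_MAPPING` warning.
#'
#' @param headers Character vector of raw header strings.
#' @param config A [load_config()] object.
#' @param sheet,workbook Provenance for the logged events.
#' @return A list with `map` (character vector, canonical name or `NA` per
#'   column) and `events`.
#' @export
map_columns <- function(headers, config, sheet = NA_character_,
                        workbook = NA_character_) {
  norm <- normalize_header(headers)
  map <- unname(config$synonyms[norm])
  events <- list()
  seen <- character(0)
  for (j in seq_along(headers)) {
    if (is_blank(headers[j])) {
      map[j] <- NA_character_
      next
    }
    if (is.na(map[j])) {
      events <- c(events, list(new_event(
        "W_UNMAPPED_COLUMN", workbook = workbook, sheet = sheet,
        column = headers[j], raw = headers[j]
      )))
      next
    }
    if (map[j] %in% seen) {
      events <- c(events, list(new_event(
        "W_DUPLICATE_MAPPING", workbook = workbook, sheet = sheet,
        column = map[j], raw = headers[j]
      )))
      map[j] <- NA_character_
      next
    }
    seen <- c(seen, map[j])
  }
  list(map = map, events = events)
}

sheet_period <- function(sheet_name) {
  m <- regmatches(sheet_name,
                  regexpr("[0-9]{4}-(0[1-9]|1[0-2])$", sheet_name))
  if (length(m) == 0) NA_character_ else m
}

# Site code (country+clinic) from the workbook file name, if it follows the
# generator's convention; NA otherwise.
workbook_site <- function(wb_name) {
  m <- regmatches(wb_name, regexec("tracker_([A-Z]{4})\\.xlsx$", wb_name))[[1]]
  if (length(m) == 0) NA_character_ else m[2]
}

#' Extract raw records from an anonymized workbook
#'
#' Iterates over every worksheet except the Patient List, detects the data
#' region, maps columns, and emits one raw record per data row with full
#' provenance. Sheets with no recognizable header are skipped with a
#' `W_NO_HEADER` event. The record's entity (patient or product) is the
#' majority entity of its mapped columns.
#'
#' @param path Path to an `.xlsx` workbook.
#' @param config A [load_config()] object.
#' @return A list with `records` (list of raw records: `provenance`,
#'   `entity`, `values` — named raw strings keyed by canonical variable —
#'   and `unmapped`) and `events`.
#' @export
extract_records <- function(path, config) {
  workbook <- read_workbook(path)
  wb_name <- basename(path)
  site <- workbook_site(wb_name)
  records <- list()
  events <- list()

  for (s in seq_along(workbook)) {
    sheet_name <- names(workbook)[s]
    if (identical(normalize_header(sheet_name), "patient list")) next
    mat <- workbook[[s]]
    region <- detect_region(mat, config)
    if (is.null(region)) {
      events <- c(events, list(new_event(
        "W_NO_HEADER", workbook = wb_name, sheet = sheet_name,
        clinic = site
      )))
      next
    }
    period <- sheet_period(sheet_name)
    mapping <- map_columns(region$headers, config, sheet = sheet_name,
                           workbook = wb_name)
    for (e in mapping$events) {
      e$clinic <- site
      e$period <- period
      events <- c(events, list(e))
    }
    map <- mapping$map
    mapped_idx <- which(!is.na(map))
    if (length(mapped_idx) == 0) next
    # entity: majority vote of the mapped columns' declared entities;
    # variables declared in both entities abstain
    ents <- config$variables$entity
    nm <- config$variables$name
    votes <- vapply(map[mapped_idx], function(v) {
      e <- unique(ents[nm == v])
      if (length(e) == 1) e else NA_character_
    }, character(1))
    n_pat <- sum(votes == "patient", na.rm = TRUE)
    n_pro <- sum(votes == "product", na.rm = TRUE)
    entity <- if (n_pro > n_pat) "product" else "patient"

    # resolve names against the chosen entity
    declared <- nm[ents == entity]
    for (j in mapped_idx) {
      if (!map[j] %in% declared) {
        events <- c(events, list(new_event(
          "W_UNMAPPED_COLUMN", workbook = wb_name, sheet = sheet_name,
          column = region$headers[j], raw = region$headers[j],
          clinic = site, period = period
        )))
        map[j] <- NA_character_
      }
    }
    mapped_idx <- which(!is.na(map))

    if (region$data_end <= region$data_start) next
    for (r0 in region$data_start:(region$data_end - 1L)) {
      r <- r0 + 1L  # 1-based
      vals <- as.list(mat[r, mapped_idx])
      names(vals) <- map[mapped_idx]
      unmapped_idx <- which(is.na(map) & !is_blank(region$headers))
      unmapped <- as.list(mat[r, unmapped_idx])
      names(unmapped) <- region$headers[unmapped_idx]
      records[[length(records) + 1]] <- list(
        provenance = list(workbook = wb_name, sheet = sheet_name,
                          row = r0, clinic = site, period = period),
        entity = entity,
        values = vals,
        unmapped = unmapped
      )
    }
  }
  list(records = records, events = events)
}
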