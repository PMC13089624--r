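#' Pseudonymization of tracker workbooks
#'
#' Anonymization happens before any other processing: patient names are
#' replaced by structured program identifiers (two-letter country code,
#' two-letter clinic code, three-digit sequence) via the workbook's own
#' "Patient List" roster sheet. Matching is exact after header-style
#' normalization — never fuzzy, because a fuzzy match risks substituting the
#' wrong patient. A name in a name-designated column that matches no roster
#' entry is replaced by the redaction token `"[UNRESOLVED]"` and logged
#' (`W_NAME_UNMATCHED`) for manual follow-up: the output fails closed rather
#' than leaking a residual name.
#'
#' @name anonymization
NULL

#' Build a name-to-identifier lookup from a workbook's Patient List
#'
#' @param workbook A workbook model from [read_workbook()].
#' @return A list of class `tf_lookup`: `map` (named character vector,
#'   normalized name -> identifier) and `events` (a `W_ID_PATTERN` event for
#'   every roster identifier that breaks the program pattern).
#' @export
build_lookup <- function(workbook) {
  sheet_names <- names(workbook)
  i <- which(normalize_header(sheet_names) == "patient list")
  if (length(i) == 0) {
    abort("build_lookup: workbook has no 'Patient List' sheet")
  }
  sheet <- workbook[[i[1]]]
  wb_name <- basename(attr(workbook, "path") %||% NA_character_)
  if (is.null(dim(sheet)) || nrow(sheet) < 1) {
    abort("build_lookup: 'Patient List' sheet is empty")
  }
  # locate the header row: a row containing both a name-ish and an id-ish
  # header; default to the first row
  norm <- apply(sheet, c(1, 2), normalize_header)
  header_row <- 1L
  for (r in seq_len(min(nrow(sheet), 5))) {
    if (any(norm[r, ] %in% c("name", "patient name", "full name")) &&
        any(norm[r, ] %in% c("patient id", "id", "identifier", "program id"))) {
      header_row <- r
      break
    }
  }
  name_col <- which(norm[header_row, ] %in%
                      c("name", "patient name", "full name"))[1]
  id_col <- which(norm[header_row, ] %in%
                    c("patient id", "id", "identifier", "program id"))[1]
  if (is.na(name_col) || is.na(id_col)) {
    name_col <- 1L
    id_col <- 2L
  }
  rows <- seq_len(nrow(sheet))
  rows <- rows[rows > header_row]
  map <- character(0)
  events <- list()
  for (r in rows) {
    nm <- sheet[r, name_col]
    id <- sheet[r, id_col]
    if (is_blank(nm) && is_blank(id)) next
    key <- normalize_header(nm)
    id <- trimws(id %||% "")
    chk <- validate_identifier(id)
    if (!chk$valid) {
      ev <- chk$events[[1]]
      ev$workbook <- wb_name
      ev$sheet <- sheet_names[i[1]]
      ev$row <- r - 1L
      events <- c(events, list(ev))
    }
    if (key %in% names(map) && !identical(unname(map[key]), id)) {
      abort(paste0("build_lookup: duplicate name '", nm,
                   "' maps to conflicting identifiers ", map[key], " and ",
                   id))
    }
    map[key] <- id
  }
  if (anyDuplicated(unname(map))) {
    abort("build_lookup: two names share one identifier")
  }
  structure(list(map = map, events = events), class = "tf_lookup")
}

#' Replace patient names with program identifiers across a workbook
#'
#' Walks every worksheet and replaces each whole cell whose normalized
#' content equals a roster name with its identifier (substring matches
#' inside free text are deliberately left alone — corrupting clinical notes
#' is worse than flagging them). Cells in name-designated columns (headers
#' listed under `anonymization: name_headers` in the configuration) that
#' match no roster entry are replaced by `"[UNRESOLVED]"` with a
#' `W_NAME_UNMATCHED` warning. The input file is never modified; the
#' deidentified copy is written to `out_dir`, which must differ from the
#' input directory.
#'
#' @param workbook A workbook model from [read_workbook()] (its `path`
#'   attribute names the output file).
#' @param lookup A [build_lookup()] result.
#' @param out_dir Output directory, distinct from the input directory.
#' @param config A [load_config()] object (supplies `name_headers`).
#' @return A list with `path` (the deidentified copy) and `events`.
#' @export
anonymize_workbook <- function(workbook, lookup, out_dir,
                               config = load_config()) {
  in_path <- attr(workbook, "path")
  if (!is.null(in_path)) {
    in_dir <- normalizePath(dirname(in_path), mustWork = FALSE)
    if (identical(in_dir, normalizePath(out_dir, mustWork = FALSE))) {
      abort("anonymize_workbook: out_dir must differ from the input directory (originals never leave their storage)")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wb_name <- basename(in_path %||% "workbook.xlsx")
  events <- list()
  out <- workbook

  for (s in seq_along(out)) {
    mat <- out[[s]]
    if (is.null(dim(mat)) || nrow(mat) == 0) next
    sheet_name <- names(out)[s]
    # whole-cell replacement of any roster name, any sheet
    norm <- matrix(normalize_header(mat), nrow = nrow(mat))
    hit <- !is.na(mat) & norm %in% names(lookup$map)
    mat[hit] <- unname(lookup$map[norm[hit]])
    # name-designated columns: anything else non-blank is redacted
    header_rows <- which(apply(norm, 1, function(r) {
      any(r %in% config$name_headers)
    }))
    if (length(header_rows) > 0) {
      hr <- header_rows[1]
      name_cols <- which(norm[hr, ] %in% config$name_headers)
      span <- data_span_rows(mat, hr)
      for (col in name_cols) {
        for (r in span) {
          v <- mat[r, col]
          if (is_blank(v) || v %in% lookup$map) next
          events <- c(events, list(new_event(
            "W_NAME_UNMATCHED", workbook = wb_name, sheet = sheet_name,
            row = r - 1L, column = "patient_id", raw = v,
            substituted = REDACTION_TOKEN
          )))
          mat[r, col] <- REDACTION_TOKEN
        }
      }
    }
    out[[s]] <- mat
  }

  out_path <- file.path(out_dir, wb_name)
  write_xlsx(out, out_path)
  list(path = out_path, events = events)
}

#' Anonymize every workbook in a directory
#'
#' Convenience wrapper: builds each workbook's lookup from its own Patient
#' List, writes deidentified copies plus an event log, and drops an
#' `_ANONYMIZED` marker file that the pipeline checks before running.
#'
#' @param in_dir Directory of raw `.xlsx` trackers.
#' @param out_dir Output directory (must differ from `in_dir`).
#' @param config A [load_config()] object.
#' @param log_path Optional JSON Lines path for the events (default
#'   `events_anonymize.jsonl` inside `out_dir`).
#' @return A list with `paths`, `events` (tibble) and `log_path`.
#' @export
anonymize_dir <- function(in_dir, out_dir, config = load_config(),
                          log_path = file.path(out_dir,
                                               "events_anonymize.jsonl")) {
  files <- sort(list.files(in_dir, pattern = "\\.xlsx$", full.names = TRUE))
  if (length(files) == 0) {
    abort(paste0("anonymize_dir: no .xlsx workbooks in ", in_dir))
  }
  events <- list()
  paths <- character(0)
  for (f in files) {
    wb <- read_workbook(f)
    lookup <- build_lookup(wb)
    res <- anonymize_workbook(wb, lookup, out_dir, config)
    events <- c(events, lookup$events, res$events)
    paths <- c(paths, res$path)
  }
  ev <- events_tibble(events)
  write_events(ev, log_path)
  writeLines("anonymized", file.path(out_dir, "_ANONYMIZED"))
  list(paths = paths, events = ev, log_path = log_path)
}
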