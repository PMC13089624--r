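#' Load stage
#'
#' Assembles cleaned records into database-ready patient and product tables
#' — columns in canonical-schema order, rows sorted by patient and date
#' (clinic, date and product for stock tables) with a deterministic
#' provenance tie-break — and serializes them to Apache Parquet in a local
#' staging directory. Sentinel values pass through unchanged; flags
#' materialize as boolean columns. The staging directory stands in for the
#' cloud warehouse a deployment would upload to: a thin uploader can consume
#' it without the pipeline knowing.
#'
#' @name loading
NULL

# Staged column layout for one entity: canonical variables in schema order
# (blood-pressure variables expand to *_systolic/*_diastolic), then flag
# columns, then provenance.
staged_columns <- function(config, entity) {
  vars <- config$variables[config$variables$entity == entity, ]
  data_cols <- list()
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    if (v$dtype == "blood_pressure") {
      data_cols[[paste0(v$name, "_systolic")]] <- "number"
      data_cols[[paste0(v$name, "_diastolic")]] <- "number"
    } else {
      data_cols[[v$name]] <- v$dtype
    }
  }
  flag_cols <- character(0)
  for (i in seq_len(nrow(vars))) {
    v <- vars[i, ]
    flag_cols <- c(flag_cols, switch(v$dtype,
      hba1c = paste0(v$name, "_threshold_exceeded"),
      height = paste0(v$name, "_unit_converted"),
      date = paste0(v$name, "_month_precision"),
      NULL
    ))
  }
  list(data = data_cols, flags = flag_cols)
}

flag_of <- function(flags, var, flag) {
  isTRUE(flag %in% (flags[[var]] %||% character(0)))
}

#' Assemble cleaned records into staged tables
#'
#' @param cleaned List of cleaned records from [clean_record()].
#' @param config A [load_config()] object.
#' @return A list with `patient` and `product` tibbles and `events`
#'   (`W_MISSING_KEY` for records lacking their entity key, which are
#'   excluded from staging but accounted for in the log). Patient rows sort
#'   by (patient_id, record_date), product rows by (clinic_code,
#'   record_date, product_name), each with a (workbook, sheet, row)
#'   provenance tie-break. A patient record with no record_date value takes
#'   the first day of its sheet's reporting period.
#' @export
assemble_tables <- function(cleaned, config) {
  events <- list()
  out <- list()
  for (entity in c("patient", "product")) {
    cols <- staged_columns(config, entity)
    recs <- Filter(function(r) identical(r$entity, entity), cleaned)
    key_var <- if (entity == "patient") "patient_id" else "product_name"

    keep <- logical(length(recs))
    for (i in seq_along(recs)) {
      key <- recs[[i]]$values[[key_var]]
      keep[i] <- !is.null(key) && !is.na(key) && nzchar(key)
      if (!keep[i]) {
        p <- recs[[i]]$provenance
        events <- c(events, list(new_event(
          "W_MISSING_KEY", workbook = p$workbook, sheet = p$sheet,
          row = p$row, column = key_var, clinic = p$clinic,
          period = p$period
        )))
      }
    }
    recs <- recs[keep]
    n <- length(recs)

    tbl <- list()
    for (col in names(cols$data)) {
      dtype <- cols$data[[col]]
      if (dtype == "date") {
        vals <- rep(as.Date(NA), n)
        for (i in seq_len(n)) {
          v <- recs[[i]]$values[[col]]
          if (!is.null(v) && !is.na(v)) vals[i] <- v
        }
        if (col == "record_date" && n > 0) {
          fill <- which(is.na(vals))
          for (i in fill) {
            per <- recs[[i]]$provenance$period
            if (!is.na(per)) vals[i] <- as.Date(paste0(per, "-01"))
          }
        }
      } else if (dtype %in% c("number", "hba1c", "height")) {
        vals <- rep(NA_real_, n)
        for (i in seq_len(n)) {
          v <- recs[[i]]$values[[col]]
          if (!is.null(v) && !is.na(v)) vals[i] <- as.numeric(v)
        }
      } else {
        vals <- rep(NA_character_, n)
        for (i in seq_len(n)) {
          v <- recs[[i]]$values[[col]]
          if (!is.null(v) && !is.na(v)) vals[i] <- as.character(v)
        }
      }
      tbl[[col]] <- vals
    }
    for (fc in cols$flags) {
      var <- sub("_(threshold_exceeded|unit_converted|month_precision)$", "",
                 fc)
      flag <- sub(paste0("^", var, "_"), "", fc)
      flag <- sub("threshold_exceeded", "threshold_exceeded", flag)
      tbl[[fc]] <- vapply(recs, function(r) flag_of(r$flags, var, flag),
                          logical(1))
    }
    tbl$workbook <- vapply(recs, function(r) r$provenance$workbook,
                           character(1))
    tbl$sheet <- vapply(recs, function(r) r$provenance$sheet, character(1))
    tbl$row <- vapply(recs, function(r) as.integer(r$provenance$row),
                      integer(1))
    tbl$clinic <- vapply(recs, function(r) r$provenance$clinic %||%
                           NA_character_, character(1))
    tbl$period <- vapply(recs, function(r) r$provenance$period %||%
                           NA_character_, character(1))
    df <- tibble::as_tibble(tbl)
    df <- if (entity == "patient") {
      dplyr::arrange(df, .data$patient_id, .data$record_date,
                     .data$workbook, .data$sheet, .data$row)
    } else {
      dplyr::arrange(df, .data$clinic_code, .data$record_date,
                     .data$product_name, .data$workbook, .data$sheet,
                     .data$row)
    }
    out[[entity]] <- df
  }
  out$events <- events
  out
}

#' Write a staged table to Apache Parquet
#'
#' Logical types are preserved (dates as date32, numbers as double,
#' booleans, UTF-8 strings) and the same table always serializes to
#' identical bytes, so reruns are verifiable by checksum.
#'
#' @param table A staged tibble from [assemble_tables()].
#' @param path Output `.parquet` path.
#' @return `path`, invisibly.
#' @export
write_staged_parquet <- function(table, path) {
  arrow::write_parquet(table, path)
  invisible(path)
}

#' Run the extract-clean-load pipeline over a directory
#'
#' For every anonymized workbook in `in_dir`: extract raw records, clean
#' every field, assemble and sort staged tables, and write
#' `patient.parquet`, `product.parquet`, `events.jsonl` and a
#' `summary.json` of run counts into `out_dir`. The pipeline refuses to run
#' on a directory lacking the `_ANONYMIZED` marker (written by
#' [anonymize_dir()]) unless `allow_unanonymized = TRUE`: anonymization
#' strictly precedes all other processing.
#'
#' @param in_dir Directory of anonymized `.xlsx` workbooks.
#' @param out_dir Staging directory for outputs (created if missing).
#' @param config A [load_config()] object.
#' @param allow_unanonymized Skip the anonymization-marker check.
#' @param csv_mirror Also write `patient.csv` / `product.csv` for desk
#'   inspection.
#' @return A list (invisible) with the staged `patient` and `product`
#'   tibbles, the `events` tibble, the `summary` list, and output `paths`.
#' @export
run_pipeline <- function(in_dir, out_dir, config = load_config(),
                         allow_unanonymized = FALSE, csv_mirror = FALSE) {
  if (!dir.exists(in_dir)) {
    abort(paste0("run_pipeline: input directory not found: ", in_dir))
  }
  if (!allow_unanonymized &&
      !file.exists(file.path(in_dir, "_ANONYMIZED"))) {
    abort(paste0(
      "run_pipeline: ", in_dir, " has no _ANONYMIZED marker; anonymize ",
      "first (or pass allow_unanonymized = TRUE for already-deidentified data)"
    ))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(in_dir, pattern = "\\.xlsx$", full.names = TRUE))
  if (length(files) == 0) {
    warn(paste0("run_pipeline: no workbooks in ", in_dir))
  }

  events <- list()
  cleaned <- list()
  for (f in files) {
    ex <- extract_records(f, config)
    events <- c(events, ex$events)
    for (rec in ex$records) {
      cr <- clean_record(rec, config)
      events <- c(events, cr$events)
      cleaned[[length(cleaned) + 1]] <- cr
    }
  }
  tables <- assemble_tables(cleaned, config)
  events <- c(events, tables$events)
  ev <- events_tibble(events)

  paths <- list(
    patient = file.path(out_dir, "patient.parquet"),
    product = file.path(out_dir, "product.parquet"),
    events = file.path(out_dir, "events.jsonl"),
    summary = file.path(out_dir, "summary.json")
  )
  write_staged_parquet(tables$patient, paths$patient)
  write_staged_parquet(tables$product, paths$product)
  write_events(ev, paths$events)
  if (csv_mirror) {
    utils::write.csv(tables$patient, file.path(out_dir, "patient.csv"),
                     row.names = FALSE)
    utils::write.csv(tables$product, file.path(out_dir, "product.csv"),
                     row.names = FALSE)
  }

  by_code <- table(ev$code)
  summary <- list(
    n_workbooks = length(files),
    n_records = length(cleaned),
    n_patient_rows = nrow(tables$patient),
    n_product_rows = nrow(tables$product),
    n_events = nrow(ev),
    n_warnings = sum(ev$severity == "warning"),
    events_by_code = as.list(setNames(as.integer(by_code), names(by_code))),
    clinics = sort(unique(stats::na.omit(c(tables$patient$clinic,
                                           tables$product$clinic)))),
    periods = sort(unique(stats::na.omit(c(tables$patient$period,
                                           tables$product$period))))
  )
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       na = "null", pretty = TRUE, digits = NA)
  invisible(list(patient = tables$patient, product = tables$product,
                 events = ev, summary = summary, paths = paths))
}
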