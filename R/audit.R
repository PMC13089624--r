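#' Data-quality audit
#'
#' Aggregates the pipeline's validation events into a per-site, per-period
#' count matrix and computes per-variable completeness over the staged
#' tables, making it straightforward to see which clinics and reporting
#' periods contribute clean data and which need follow-up. Completeness of
#' a variable is the fraction of staged rows carrying a *usable* value —
#' missing cells and sentinel substitutions both count against it, and the
#' denominator is all rows of the entity, so a column a site's template
#' simply lacks (e.g. insulin types before 2024) shows up as incompleteness
#' rather than disappearing.
#'
#' @name auditing
NULL

SENTINEL_NUMERIC_DEFAULT <- 999999

#' Build an audit report from an event log and staged tables
#'
#' @param events_path Path to a JSON Lines event log (malformed lines are
#'   counted under code `PARSE_ERROR`, never dropped).
#' @param tables A list with `patient` and `product` staged tibbles (as
#'   returned by [run_pipeline()]), or a staging directory containing
#'   `patient.parquet` and `product.parquet`.
#' @param config A [load_config()] object (supplies the sentinel policy and
#'   schema).
#' @return A list of class `tf_audit`: `counts` (tibble clinic x period x
#'   code with `n`), `completeness` (tibble entity x variable with
#'   `n_rows`, `n_usable`, `completeness`), and `totals`.
#' @export
build_audit <- function(events_path, tables, config = load_config()) {
  events <- read_events(events_path)
  if (is.character(tables) && length(tables) == 1) {
    tables <- list(
      patient = arrow::read_parquet(file.path(tables, "patient.parquet")),
      product = arrow::read_parquet(file.path(tables, "product.parquet"))
    )
  }
  counts <- events |>
    dplyr::mutate(
      clinic = dplyr::coalesce(.data$clinic, "unknown"),
      period = dplyr::coalesce(.data$period, "unknown")
    ) |>
    dplyr::count(.data$clinic, .data$period, .data$code, name = "n") |>
    dplyr::arrange(.data$clinic, .data$period, .data$code)

  sent_num <- config$sentinels$numeric
  sent_date <- config$sentinels$date
  comp <- list()
  for (entity in c("patient", "product")) {
    tab <- tables[[entity]]
    cols <- staged_columns(config, entity)
    for (col in names(cols$data)) {
      v <- tab[[col]]
      n <- nrow(tab)
      usable <- if (n == 0) logical(0) else if (inherits(v, "Date")) {
        !is.na(v) & v != sent_date
      } else if (is.numeric(v)) {
        !is.na(v) & v != sent_num
      } else {
        !is.na(v) & nzchar(v)
      }
      comp[[length(comp) + 1]] <- tibble::tibble(
        entity = entity, variable = col, n_rows = n,
        n_usable = sum(usable),
        completeness = if (n == 0) NA_real_ else sum(usable) / n
      )
    }
  }
  completeness <- dplyr::bind_rows(comp)

  totals <- list(
    n_events = nrow(events),
    n_warnings = sum(events$severity == "warning", na.rm = TRUE),
    n_info = sum(events$severity == "info", na.rm = TRUE),
    n_parse_errors = sum(events$code == "PARSE_ERROR"),
    n_patient_rows = nrow(tables$patient),
    n_product_rows = nrow(tables$product)
  )
  structure(list(counts = counts, completeness = completeness,
                 totals = totals), class = "tf_audit")
}

#' Render an audit report to disk
#'
#' Writes the report as machine-readable JSON at `path` and a
#' human-readable aligned text summary alongside (same name, `.txt`).
#' Ordering is stable (clinic, period, code lexicographic), so rendering
#' the same report twice yields identical bytes.
#'
#' @param report A `tf_audit` from [build_audit()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path) {
  stopifnot(inherits(report, "tf_audit"))
  payload <- list(
    totals = report$totals,
    counts = report$counts,
    completeness = report$completeness
  )
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       na = "null", pretty = TRUE, digits = NA)

  txt_path <- sub("\\.json$", ".txt", path)
  if (identical(txt_path, path)) txt_path <- paste0(path, ".txt")
  lines <- c(
    "Data-quality audit",
    "==================",
    sprintf("events: %d (%d warnings, %d info, %d parse errors)",
            report$totals$n_events, report$totals$n_warnings,
            report$totals$n_info, report$totals$n_parse_errors),
    sprintf("staged rows: %d patient, %d product",
            report$totals$n_patient_rows, report$totals$n_product_rows),
    "",
    "Event counts by site and period:",
    if (nrow(report$counts) == 0) "  (none)" else sprintf(
      "  %-8s %-8s %-24s %6d", report$counts$clinic, report$counts$period,
      report$counts$code, report$counts$n
    ),
    "",
    "Completeness by variable:",
    sprintf("  %-8s %-28s %6.3f  (%d/%d)",
            report$completeness$entity, report$completeness$variable,
            report$completeness$completeness,
            report$completeness$n_usable, report$completeness$n_rows)
  )
  writeLines(lines, txt_path, useBytes = TRUE)
  invisible(path)
}
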