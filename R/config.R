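#' Load and validate a pipeline configuration
#'
#' The whole pipeline is configuration-driven: a single YAML file declares
#' the canonical schema (one entry per variable, with entity, dtype,
#' clinically plausible bounds and allowed categorical values), the synonym
#' map from raw column-header variants to canonical variables, the sentinel
#' policy, cleaning thresholds, and the headers that designate patient-name
#' columns. Everything is validated up front so a broken configuration fails
#' at startup with the offending key named, never mid-run.
#'
#' @param path Path to a YAML configuration file. Defaults to the shipped
#'   configuration (see [default_config_path()]).
#' @return An object of class `tf_config`: a list with elements
#'   \describe{
#'     \item{variables}{tibble with columns `name`, `entity`, `dtype`,
#'       `required`, `min`, `max`, `allowed` (list-column)}
#'     \item{synonyms}{named character vector, normalized header -> canonical
#'       variable name}
#'     \item{sentinels}{list with `numeric` (default 999999) and `date`
#'       (a `Date`, default 9999-12-31)}
#'     \item{validation}{list of cleaning thresholds: `height_cm_threshold`,
#'       `height_m_bounds`, `bp_systolic_bounds`, `bp_diastolic_bounds`,
#'       `serial_window`}
#'     \item{name_headers}{normalized headers designating name columns}
#'     \item{patient_variable_count, product_variable_count}{number of
#'       distinct canonical variables per entity reachable via the synonym
#'       map}
#'   }
#' @examples
#' cfg <- load_config()
#' cfg$patient_variable_count
#' @export
load_config <- function(path = default_config_path()) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path))
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) abort(paste0("malformed YAML in ", path, ": ",
                                     conditionMessage(e)))
  )
  for (key in c("variables", "synonyms", "sentinels", "validation")) {
    if (is.null(raw[[key]]) || length(raw[[key]]) == 0) {
      abort(paste0("config error: section '", key, "' is missing or empty"))
    }
  }

  dtypes <- c("number", "date", "text", "category", "hba1c",
              "blood_pressure", "height")
  bounded_dtypes <- c("number", "hba1c", "height")

  vars <- dplyr::bind_rows(lapply(raw$variables, function(v) {
    if (is.null(v$name) || is.null(v$entity) || is.null(v$dtype)) {
      abort("config error: every entry of 'variables' needs name, entity, dtype")
    }
    if (!v$entity %in% c("patient", "product")) {
      abort(paste0("config error: variables/", v$name,
                   ": unknown entity '", v$entity, "'"))
    }
    if (!v$dtype %in% dtypes) {
      abort(paste0("config error: variables/", v$name,
                   ": unknown dtype '", v$dtype, "'"))
    }
    has_bounds <- !is.null(v$bounds)
    if (has_bounds != (v$dtype %in% bounded_dtypes)) {
      abort(paste0("config error: variables/", v$name,
                   ": bounds must be present iff dtype is one of ",
                   paste(bounded_dtypes, collapse = "/")))
    }
    if (has_bounds) {
      if (is.null(v$bounds$min) || is.null(v$bounds$max) ||
          !(v$bounds$min < v$bounds$max)) {
        abort(paste0("config error: variables/", v$name,
                     ": bounds need min < max"))
      }
    }
    has_allowed <- !is.null(v$allowed_values) && length(v$allowed_values) > 0
    if (has_allowed != identical(v$dtype, "category")) {
      abort(paste0("config error: variables/", v$name,
                   ": allowed_values must be non-empty iff dtype is category"))
    }
    tibble::tibble(
      name = v$name, entity = v$entity, dtype = v$dtype,
      required = isTRUE(v$required),
      min = if (has_bounds) as.numeric(v$bounds$min) else NA_real_,
      max = if (has_bounds) as.numeric(v$bounds$max) else NA_real_,
      allowed = list(if (has_allowed) as.character(v$allowed_values)
                     else character(0))
    )
  }))
  dup <- vars |>
    dplyr::count(.data$entity, .data$name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("config error: variables/", dup$name[1],
                 ": duplicate name within entity '", dup$entity[1], "'"))
  }

  syn_raw <- raw$synonyms
  keys <- normalize_header(names(syn_raw))
  if (anyDuplicated(keys)) {
    abort(paste0("config error: synonyms: duplicate normalized header '",
                 keys[duplicated(keys)][1], "'"))
  }
  targets <- vapply(syn_raw, as.character, character(1))
  bad <- setdiff(unique(targets), vars$name)
  if (length(bad) > 0) {
    abort(paste0("config error: synonyms: target '", bad[1],
                 "' is not a declared variable"))
  }
  synonyms <- setNames(unname(targets), keys)

  sentinels <- list(
    numeric = as.numeric(raw$sentinels$numeric %||% 999999),
    date = as.Date(as.character(raw$sentinels$date %||% "9999-12-31"))
  )
  bounded <- vars[!is.na(vars$min), ]
  inside <- sentinels$numeric >= bounded$min & sentinels$numeric <= bounded$max
  if (any(inside)) {
    abort(paste0("config error: sentinels/numeric: ", sentinels$numeric,
                 " lies inside the bounds of variable '",
                 bounded$name[which(inside)[1]], "'"))
  }

  val <- raw$validation
  as_bounds <- function(x, key) {
    if (is.null(x$min) || is.null(x$max) || !(x$min < x$max)) {
      abort(paste0("config error: validation/", key, ": need min < max"))
    }
    c(min = as.numeric(x$min), max = as.numeric(x$max))
  }
  validation <- list(
    height_cm_threshold = as.numeric(val$height_cm_threshold %||% 50),
    height_m_bounds = as_bounds(val$height_m_bounds %||%
                                  list(min = 0.3, max = 2.5), "height_m_bounds"),
    bp_systolic_bounds = as_bounds(val$bp_systolic_bounds %||%
                                     list(min = 50, max = 250), "bp_systolic_bounds"),
    bp_diastolic_bounds = as_bounds(val$bp_diastolic_bounds %||%
                                      list(min = 30, max = 150), "bp_diastolic_bounds"),
    serial_window = as_bounds(val$serial_window %||%
                                list(min = 20000, max = 60000), "serial_window")
  )
  if (validation$height_cm_threshold <= 0) {
    abort("config error: validation/height_cm_threshold must be positive")
  }

  name_headers <- normalize_header(
    as.character(raw$anonymization$name_headers %||%
                   c("name", "patient name", "full name"))
  )

  patient_vars <- vars$name[vars$entity == "patient"]
  product_vars <- vars$name[vars$entity == "product"]
  cfg <- structure(list(
    variables = vars,
    synonyms = synonyms,
    sentinels = sentinels,
    validation = validation,
    name_headers = name_headers,
    patient_variable_count = length(intersect(unique(targets), patient_vars)),
    product_variable_count = length(intersect(unique(targets), product_vars)),
    path = path
  ), class = "tf_config")
  cfg
}

#' Path of the configuration shipped with the package
#'
#' @return Filesystem path of the default YAML configuration.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "trackerforge",
              mustWork = TRUE)
}

#' @export
print.tf_config <- function(x, ...) {
  cat("<tf_config>", basename(x$path), "\n")
  cat("  variables:", nrow(x$variables),
      sprintf("(%d patient, %d product)",
              sum(x$variables$entity == "patient"),
              sum(x$variables$entity == "product")), "\n")
  cat("  synonyms :", length(x$synonyms), "entries ->",
      x$patient_variable_count, "patient /",
      x$product_variable_count, "product variables\n")
  cat("  sentinels: numeric", x$sentinels$numeric,
      "| date", format(x$sentinels$date), "\n")
  invisible(x)
}

# Look up one variable definition; returns a one-row tibble or NULL.
var_def <- function(config, entity, name) {
  i <- which(config$variables$entity == entity & config$variables$name == name)
  if (length(i) == 0) return(NULL)
  config$variables[i[1], ]
}
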