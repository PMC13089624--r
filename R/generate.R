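#' Synthetic tracker generation
#'
#' No real tracker data can ship with the package, so a seeded generator
#' emulates the *structural* messiness of a multi-country program's monthly
#' Excel trackers: per-clinic workbooks with a "Patient List" roster sheet
#' and one worksheet per reporting month, site-specific column-header
#' variants drawn from the synonym map, decorative title rows, end markers,
#' template drift (insulin-type columns only from 2024 onward), and injected
#' corruptions — serial-number and multi-format dates, dates embedded in
#' prose, inequality-prefixed HbA1c, combined blood-pressure strings,
#' centimetre heights, free-text categoricals, typos, blanks and
#' out-of-range values. Every generated data cell is recorded in a
#' ground-truth manifest so the cleaning stage can be scored exactly.
#'
#' @name synthetic-tracker
NULL

PROGRAM_COUNTRIES <- c("KH", "LA", "MM", "MY", "PH", "TH", "VN")

CORRUPTION_CLASSES <- c(
  "none", "date_format_variant", "excel_serial", "embedded_date",
  "hba1c_inequality", "bp_combined", "height_cm", "typo_unrecoverable",
  "blank", "out_of_range", "category_freetext"
)

# Classes whose true value the cleaner can reconstruct.
RECOVERABLE_CLASSES <- c("date_format_variant", "excel_serial",
                         "embedded_date", "hba1c_inequality", "bp_combined",
                         "height_cm")
UNRECOVERABLE_CLASSES <- c("typo_unrecoverable", "blank", "out_of_range",
                           "category_freetext")

#' Default per-cell corruption rates
#'
#' Probabilities that a generated cell of an applicable dtype receives each
#' corruption class, drawn independently per cell. The defaults lean toward
#' the formatting deviations that dominate real trackers (variant date
#' formats, centimetre heights) over outright errors.
#'
#' @return Named numeric vector of probabilities.
#' @export
default_corruption_rates <- function() {
  c(date_format_variant = 0.15, excel_serial = 0.10, embedded_date = 0.03,
    hba1c_inequality = 0.10, bp_combined = 0.10, height_cm = 0.30,
    typo_unrecoverable = 0.02, blank = 0.05, out_of_range = 0.02,
    category_freetext = 0.05)
}

#' Build a generator configuration
#'
#' Defaults mirror the scale of the program the package targets: 7
#' countries, 42 clinics, ~1400 patients, trackers spanning 2017–2025.
#' Tests and examples use far smaller settings.
#'
#' @param n_countries Number of countries (two-letter codes).
#' @param n_clinics Number of clinics; each clinic gets one workbook.
#' @param n_patients Total patients, distributed evenly across clinics.
#' @param year_range Integer vector `c(first, last)` of tracker years.
#' @param n_months Number of monthly worksheets per workbook, drawn without
#'   replacement from the year range.
#' @param corruption_rates See [default_corruption_rates()].
#' @param seed Integer seed; same configuration and seed reproduce
#'   byte-identical workbooks and manifest.
#' @return A list of class `tf_generator_config`.
#' @export
generator_config <- function(n_countries = 7, n_clinics = 42,
                             n_patients = 1400,
                             year_range = c(2017, 2025), n_months = 12,
                             corruption_rates = default_corruption_rates(),
                             seed = 1) {
  if (n_clinics < n_countries) {
    abort("generator config: n_clinics must be >= n_countries")
  }
  if (year_range[1] <= 1900 || year_range[2] >= 9998 ||
      year_range[1] > year_range[2]) {
    abort("generator config: year_range must be ordered and within (1900, 9998)")
  }
  rates <- default_corruption_rates()
  rates[names(corruption_rates)] <- corruption_rates
  if (any(rates < 0 | rates > 1)) {
    abort("generator config: corruption rates must lie in [0, 1]")
  }
  structure(list(
    n_countries = as.integer(n_countries),
    n_clinics = as.integer(n_clinics),
    n_patients = as.integer(n_patients),
    year_range = as.integer(year_range),
    n_months = as.integer(n_months),
    corruption_rates = rates,
    seed = as.integer(seed)
  ), class = "tf_generator_config")
}

FIRST_NAMES <- c(
  "Anna", "Bora", "Chan", "Dara", "Ema", "Fay", "Gita", "Hana", "Ivan",
  "Jena", "Kiri", "Lina", "Mai", "Nita", "Omar", "Pia", "Quan", "Rina",
  "Sok", "Tara", "Uma", "Vann", "Wila", "Xuan", "Yani", "Zin", "Amir",
  "Binh", "Chau", "Dawt", "Esin", "Fara", "Giang", "Hnin", "Indra", "Jaya",
  "Khin", "Long", "Minh", "Nary"
)
LAST_NAMES <- c(
  "Aung", "Bopha", "Chea", "Duong", "Eang", "Fong", "Goh", "Huynh", "Ith",
  "Jaafar", "Keo", "Lim", "Mao", "Nguyen", "Ong", "Phan", "Rith", "Sok",
  "Tan", "Ung", "Vong", "Win", "Xay", "Yusof", "Zaw", "Bunthan", "Chhay",
  "Devi", "Espino", "Flores", "Garcia", "Hlaing", "Inthavong", "Javier",
  "Kyaw", "Luang", "Myint", "Noor", "Oo", "Phommasane"
)

pick1 <- function(x) x[[sample.int(length(x), 1)]]

#' Generate a synthetic Patient List roster
#'
#' Produces `n` unique synthetic full names paired with sequential program
#' identifiers `<country><clinic>001` onward. Uses the current RNG state;
#' seed externally (e.g. via [generate_program()] or `withr::with_seed()`)
#' for reproducibility.
#'
#' @param n Number of patients (0–999; identifiers are three-digit).
#' @param country_code,clinic_code Two-uppercase-letter codes.
#' @return A tibble with columns `name` and `identifier`.
#' @examples
#' withr::with_seed(7, generate_patient_list(3, "LA", "VT"))
#' @export
generate_patient_list <- function(n, country_code, clinic_code) {
  stopifnot(grepl("^[A-Z]{2}$", country_code),
            grepl("^[A-Z]{2}$", clinic_code))
  if (n > 999) {
    abort("generate_patient_list: identifier sequence exhausted (n > 999)")
  }
  if (n == 0) {
    return(tibble::tibble(name = character(0), identifier = character(0)))
  }
  combos <- sample.int(length(FIRST_NAMES) * length(LAST_NAMES), n)
  first <- FIRST_NAMES[((combos - 1) %% length(FIRST_NAMES)) + 1]
  last <- LAST_NAMES[((combos - 1) %/% length(FIRST_NAMES)) + 1]
  tibble::tibble(
    name = paste(first, last),
    identifier = render_identifier(country_code, clinic_code, seq_len(n))
  )
}

# One typographic edit that is guaranteed to miss every roster name after
# normalization (a swap of identical letters, or a doubled space, would
# otherwise be a no-op and not a misspelling at all).
misspell <- function(name, avoid = character(0)) {
  avoid <- c(avoid, normalize_header(name))
  for (attempt in 1:25) {
    chars <- strsplit(name, "")[[1]]
    mode <- pick1(c("drop", "swap", "double"))
    i <- sample.int(max(length(chars) - 1, 1), 1)
    out <- switch(mode,
      drop = chars[-i],
      swap = { tmp <- chars[i]; chars[i] <- chars[i + 1]
               chars[i + 1] <- tmp; chars },
      double = append(chars, chars[i], after = i)
    )
    cand <- paste(out, collapse = "")
    if (!(normalize_header(cand) %in% avoid)) return(cand)
  }
  paste0(name, "q")
}

PRODUCT_CATALOG <- tibble::tibble(
  product_name = c("Insulin NPH 10ml vial", "Insulin Regular 10ml vial",
                   "Insulin Glargine pen", "Insulin Aspart pen",
                   "Insulin premix 30/70 vial", "Syringe 1ml U-100",
                   "Pen needles 4mm", "Glucometer", "Test strips box 50",
                   "Ketone strips box 10", "Lancets box 100",
                   "Glucagon kit"),
  product_category = c("Insulin", "Insulin", "Insulin", "Insulin", "Insulin",
                       "Consumable", "Consumable", "Device", "Consumable",
                       "Consumable", "Consumable", "Medication"),
  unit = c("vial", "vial", "pen", "pen", "vial", "piece", "box", "piece",
           "box", "box", "box", "kit")
)

# Variables a patient sheet always carries (name column handled separately).
PATIENT_CORE_VARS <- c("date_of_birth", "sex", "hba1c", "blood_pressure",
                       "height", "weight", "insulin_regimen",
                       "patient_status", "visit_date", "notes")
INSULIN_TYPE_VARS <- c("insulin_type_basal", "insulin_type_bolus",
                       "insulin_type_premixed")
PATIENT_EXTRA_VARS <- c("age", "diagnosis_date", "diabetes_type",
                        "dka_at_diagnosis", "fasting_glucose",
                        "insulin_dose_total", "injections_per_day",
                        "smbg_per_week", "severe_hypo_count",
                        "education_sessions", "urine_protein",
                        "glucometer_owned", "next_visit_date")

PRODUCT_SHEET_VARS <- c("product_name", "product_category", "unit",
                        "quantity_received", "quantity_distributed",
                        "stock_on_hand", "batch_number", "expiry_date",
                        "unit_cost", "currency", "clinic_code",
                        "record_date")

# Sample one raw header spelling for a canonical variable: a synonym key
# re-cased the way sites actually type headers.
header_variant <- function(var, config) {
  keys <- names(config$synonyms)[config$synonyms == var]
  key <- pick1(keys)
  style <- pick1(c("title", "upper", "as-is"))
  switch(style,
    title = gsub("\\b([a-z])", "\\U\\1", key, perl = TRUE),
    upper = toupper(key),
    key
  )
}

draw_class <- function(applicable, rates) {
  p <- rates[applicable]
  u <- runif(1)
  cum <- cumsum(p)
  i <- which(u <= cum)
  if (length(i) == 0) "none" else applicable[i[1]]
}

APPLICABLE <- list(
  date = c("date_format_variant", "excel_serial", "embedded_date",
           "typo_unrecoverable", "blank"),
  hba1c = c("hba1c_inequality", "out_of_range", "typo_unrecoverable",
            "blank"),
  blood_pressure = c("bp_combined", "typo_unrecoverable", "blank"),
  height = c("height_cm", "out_of_range", "typo_unrecoverable", "blank"),
  number = c("out_of_range", "typo_unrecoverable", "blank"),
  category = c("category_freetext", "blank"),
  text = c("blank")
)

DATE_TYPOS <- c("n/a", "not recorded", "pending", "??")
NUM_TYPOS <- c("abc", "n/a", "?", "-")
FREE_TEXTS <- c("mixed scheme am/pm", "see notes", "local protocol",
                "as before")
NOTE_TEXTS <- c("doing well", "missed last visit", "new meter given",
                "reviewed by doctor", "family counselled")

excel_serial_of <- function(d) {
  as.integer(round(as.numeric(d - as.Date("1899-12-30"))))
}

# Render one cell given its dtype, true value and corruption class.
# Returns list(rendered, true) — true may be adjusted (month-precision
# variants truncate the truth to the first of the month).
render_cell <- function(dtype, true, class, vd = NULL) {
  if (class == "blank") return(list(rendered = "", true = true))
  switch(dtype,
    date = {
      d <- as.Date(true)
      switch(class,
        none = list(rendered = format(d, "%Y-%m-%d"), true = true),
        date_format_variant = {
          variant <- pick1(c("dmy_name", "my_name", "dmy_slash"))
          switch(variant,
            dmy_name = list(rendered = format(d, "%d-%b-%Y"), true = true),
            my_name = {
              first <- as.Date(format(d, "%Y-%m-01"))
              list(rendered = format(d, "%b %Y"),
                   true = format(first, "%Y-%m-%d"))
            },
            dmy_slash = list(
              rendered = sprintf("%02d/%02d/%04d",
                                 as.integer(format(d, "%d")),
                                 as.integer(format(d, "%m")),
                                 as.integer(format(d, "%Y"))),
              true = true
            )
          )
        },
        excel_serial = list(rendered = as.character(excel_serial_of(d)),
                            true = true),
        embedded_date = list(
          rendered = paste0("recorded ", format(d, "%d-%b-%Y"), " at clinic"),
          true = true
        ),
        typo_unrecoverable = list(rendered = pick1(DATE_TYPOS), true = true)
      )
    },
    hba1c = switch(class,
      none = list(rendered = true, true = true),
      hba1c_inequality = list(
        rendered = paste0(pick1(c("<", "> ", ">", "< ")), true), true = true
      ),
      out_of_range = list(rendered = pick1(c("30", "28.5", "26.1")),
                          true = true),
      typo_unrecoverable = list(rendered = pick1(c("high", "n/a", "-")),
                                true = true)
    ),
    blood_pressure = switch(class,
      none = list(rendered = true, true = true),
      bp_combined = {
        parts <- strsplit(true, "/", fixed = TRUE)[[1]]
        list(rendered = paste0(parts[1], " / ", parts[2],
                               pick1(c(" mmHg", " mm Hg", ""))),
             true = true)
      },
      typo_unrecoverable = list(
        rendered = pick1(c("high", "120-80", "n/a")), true = true
      )
    ),
    height = switch(class,
      none = list(rendered = true, true = true),
      height_cm = list(
        rendered = sprintf("%.0f", as.numeric(true) * 100), true = true
      ),
      out_of_range = list(rendered = pick1(c("3.20", "0.10", "2.80")),
                          true = true),
      typo_unrecoverable = list(rendered = pick1(NUM_TYPOS), true = true)
    ),
    number = switch(class,
      none = list(rendered = true, true = true),
      out_of_range = {
        hi <- if (!is.null(vd) && !is.na(vd$max)) vd$max * 2 + 1 else 1e5
        list(rendered = format(hi, scientific = FALSE), true = true)
      },
      typo_unrecoverable = list(rendered = pick1(NUM_TYPOS), true = true)
    ),
    category = switch(class,
      none = list(rendered = true, true = true),
      category_freetext = list(rendered = pick1(FREE_TEXTS), true = true)
    ),
    text = list(rendered = true, true = true)
  )
}

true_value_for <- function(dtype, var, vd, period_start) {
  switch(dtype,
    date = {
      d <- switch(var,
        date_of_birth = as.Date("2000-01-01") + sample.int(8500, 1),
        visit_date = period_start + sample.int(27, 1),
        next_visit_date = period_start + 28 + sample.int(31, 1),
        expiry_date = period_start + 90 + sample.int(700, 1),
        record_date = period_start,
        period_start - sample.int(2000, 1)
      )
      format(d, "%Y-%m-%d")
    },
    hba1c = sprintf("%.1f", runif(1, 5, 14)),
    blood_pressure = paste0(sample(90:140, 1), "/", sample(55:90, 1)),
    height = sprintf("%.2f", runif(1, 0.9, 1.8)),
    number = {
      lo <- if (!is.na(vd$min)) vd$min else 0
      hi <- if (!is.na(vd$max)) vd$max else 100
      sprintf("%.1f", runif(1, lo + 0.05 * (hi - lo), lo + 0.6 * (hi - lo)))
    },
    category = pick1(vd$allowed[[1]]),
    text = pick1(NOTE_TEXTS)
  )
}

#' Generate a synthetic multi-clinic tracker program
#'
#' Writes one workbook per clinic into `out_dir` (named
#' `tracker_<COUNTRY><CLINIC>.xlsx`), each containing a "Patient List"
#' roster and one worksheet per sampled reporting month (plus a
#' `Products YYYY-MM` stock sheet per month), and a per-cell ground-truth
#' manifest (`manifest.json`). Sheets for months before 2024-01 omit the
#' insulin-type columns, emulating template drift. Identical configuration
#' and seed reproduce byte-identical outputs.
#'
#' @param config A [generator_config()].
#' @param out_dir Writable output directory (created if missing).
#' @param pipeline_config A [load_config()] object supplying the synonym
#'   map the header variants are drawn from.
#' @return A list with `workbooks` (paths), `manifest` (tibble with columns
#'   `workbook`, `sheet`, `row`, `col` (0-based), `entity`, `variable`,
#'   `true_value`, `rendered_value`, `corruption_class`), and
#'   `manifest_path`.
#' @export
generate_program <- function(config = generator_config(), out_dir,
                             pipeline_config = load_config()) {
  stopifnot(inherits(config, "tf_generator_config"))
  if (config$n_patients <= 0) {
    abort("generate_program: need at least one patient")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create out_dir: ", out_dir))

  withr::with_seed(config$seed, {
    generate_program_impl(config, out_dir, pipeline_config)
  })
}

generate_program_impl <- function(config, out_dir, pcfg) {
  rates <- config$corruption_rates
  countries <- PROGRAM_COUNTRIES
  if (config$n_countries > length(countries)) {
    extra <- apply(expand.grid(LETTERS, LETTERS), 1, paste, collapse = "")
    countries <- c(countries, setdiff(extra, countries))
  }
  countries <- countries[seq_len(config$n_countries)]

  all_pairs <- apply(expand.grid(LETTERS, LETTERS)[, c(2, 1)], 1,
                     paste, collapse = "")
  clinic_codes <- sample(all_pairs, config$n_clinics)
  clinic_country <- countries[((seq_len(config$n_clinics) - 1) %%
                                 config$n_countries) + 1]

  base <- config$n_patients %/% config$n_clinics
  extra_n <- config$n_patients %% config$n_clinics
  clinic_n <- rep(base, config$n_clinics) +
    c(rep(1, extra_n), rep(0, config$n_clinics - extra_n))

  months_all <- seq.Date(as.Date(sprintf("%d-01-01", config$year_range[1])),
                         as.Date(sprintf("%d-12-01", config$year_range[2])),
                         by = "month")
  n_months <- min(config$n_months, length(months_all))
  months <- sort(sample(months_all, n_months))

  manifest <- list()
  workbooks <- character(config$n_clinics)

  for (ci in seq_len(config$n_clinics)) {
    country <- clinic_country[ci]
    clinic <- clinic_codes[ci]
    site <- paste0(country, clinic)
    wb_name <- paste0("tracker_", site, ".xlsx")

    roster <- generate_patient_list(clinic_n[ci], country, clinic)

    extra_vars <- sample(PATIENT_EXTRA_VARS,
                         sample(4:8, 1))
    tmpl_vars <- c(PATIENT_CORE_VARS, extra_vars, INSULIN_TYPE_VARS)
    tmpl_vars <- sample(tmpl_vars)  # per-clinic column order
    headers <- vapply(tmpl_vars, header_variant, character(1), config = pcfg)
    name_header <- pick1(c("Name", "Patient Name", "Full Name"))
    has_title <- runif(1) < 0.5
    has_end <- runif(1) < 0.5

    prod_idx <- sort(sample.int(nrow(PRODUCT_CATALOG), sample(6:10, 1)))
    prod_headers <- vapply(PRODUCT_SHEET_VARS, header_variant,
                           character(1), config = pcfg)

    sheets <- list()
    sheets[["Patient List"]] <- rbind(
      c("Name", "Patient ID"),
      as.matrix(roster)
    )

    for (mi in seq_along(months)) {
      period_start <- months[mi]
      period <- format(period_start, "%Y-%m")
      pre2024 <- period_start < as.Date("2024-01-01")
      use <- if (pre2024) tmpl_vars[!tmpl_vars %in% INSULIN_TYPE_VARS]
             else tmpl_vars
      use_headers <- headers[match(use, tmpl_vars)]

      n_head <- if (has_title) 1L else 0L
      nrows <- n_head + 1L + nrow(roster) + (if (has_end) 2L else 0L)
      mat <- matrix("", nrow = nrows, ncol = length(use) + 1)
      if (has_title) mat[1, 1] <- paste("Tracker", site, "monthly report")
      header_row <- n_head + 1L
      mat[header_row, ] <- c(name_header, use_headers)

      for (pi in seq_len(nrow(roster))) {
        r <- header_row + pi
        # name column
        class <- draw_class("typo_unrecoverable", rates)
        rendered <- if (class == "typo_unrecoverable") {
          misspell(roster$name[pi], normalize_header(roster$name))
        } else roster$name[pi]
        mat[r, 1] <- rendered
        manifest[[length(manifest) + 1]] <- list(
          workbook = wb_name, sheet = period, row = r - 1L, col = 0L,
          entity = "patient", variable = "patient_id",
          true_value = roster$identifier[pi], rendered_value = rendered,
          corruption_class = class
        )
        for (vi in seq_along(use)) {
          var <- use[vi]
          vd <- var_def(pcfg, "patient", var)
          dtype <- vd$dtype
          akey <- if (dtype %in% names(APPLICABLE)) dtype else "text"
          true <- true_value_for(dtype, var, vd, period_start)
          class <- draw_class(APPLICABLE[[akey]], rates)
          cell <- render_cell(dtype, true, class, vd)
          mat[r, vi + 1] <- cell$rendered
          manifest[[length(manifest) + 1]] <- list(
            workbook = wb_name, sheet = period, row = r - 1L, col = vi,
            entity = "patient", variable = var, true_value = cell$true,
            rendered_value = cell$rendered, corruption_class = class
          )
        }
      }
      if (has_end) {
        mat[header_row + nrow(roster) + 1, 1] <- "END"
        mat[header_row + nrow(roster) + 2, 1] <- "do not edit below this line"
      }
      sheets[[period]] <- mat

      # product stock sheet for the same month
      pmat <- matrix("", nrow = 1L + length(prod_idx),
                     ncol = length(PRODUCT_SHEET_VARS))
      pmat[1, ] <- unname(prod_headers)
      psheet <- paste("Products", period)
      for (ri in seq_along(prod_idx)) {
        item <- PRODUCT_CATALOG[prod_idx[ri], ]
        for (vi in seq_along(PRODUCT_SHEET_VARS)) {
          var <- PRODUCT_SHEET_VARS[vi]
          vd <- var_def(pcfg, "product", var)
          dtype <- vd$dtype
          true <- switch(var,
            product_name = item$product_name,
            product_category = item$product_category,
            unit = item$unit,
            batch_number = paste0("B", sample(1000:9999, 1)),
            clinic_code = clinic,
            true_value_for(dtype, var, vd, period_start)
          )
          class <- if (var %in% c("product_name", "clinic_code", "unit",
                                  "batch_number")) {
            "none"  # key and join columns stay clean
          } else {
            akey <- if (dtype %in% names(APPLICABLE)) dtype else "text"
            draw_class(APPLICABLE[[akey]], rates)
          }
          cell <- render_cell(dtype, true, class, vd)
          pmat[1 + ri, vi] <- cell$rendered
          manifest[[length(manifest) + 1]] <- list(
            workbook = wb_name, sheet = psheet, row = ri, col = vi - 1L,
            entity = "product", variable = var, true_value = cell$true,
            rendered_value = cell$rendered, corruption_class = class
          )
        }
      }
      sheets[[psheet]] <- pmat
    }

    path <- file.path(out_dir, wb_name)
    write_xlsx(sheets, path)
    workbooks[ci] <- path
  }

  manifest_tbl <- dplyr::bind_rows(lapply(manifest, tibble::as_tibble))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest_tbl, manifest_path, dataframe = "rows",
                       na = "null", digits = NA)
  list(workbooks = workbooks, manifest = manifest_tbl,
       manifest_path = manifest_path)
}

#' Read a ground-truth manifest written by [generate_program()]
#'
#' @param path Path to `manifest.json`.
#' @return The manifest tibble.
#' @export
read_manifest <- function(path) {
  df <- jsonlite::fromJSON(path)
  tibble::as_tibble(df) |>
    dplyr::mutate(row = as.integer(.data$row), col = as.integer(.data$col))
}
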