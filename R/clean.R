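#' Cleaning stage
#'
#' Every extracted cell passes through a dtype-specific cleaner. The
#' contract throughout is *never drop, always flag*: a value that cannot be
#' converted or is clinically implausible is replaced by a conspicuous
#' sentinel (999999 for numbers, 9999-12-31 for dates) and a coded
#' validation event is emitted, so downstream analysts can trace exactly
#' where quality issues originate. Blank cells are ordinary missing values —
#' no sentinel, no event — which keeps missingness distinct from error.
#'
#' Each cell-level cleaner returns a list with elements `value` (typed
#' payload), `is_sentinel` (logical), `flags` (character subset of
#' `threshold_exceeded`, `month_precision`, `unit_converted`) and `events`
#' (list of validation events, see [events_tibble()]).
#'
#' @name cleaning
NULL

#' Default sentinel policy
#'
#' @return A list with `numeric` (999999) and `date` (`9999-12-31`), the
#'   conspicuous out-of-range placeholders substituted for unconvertible or
#'   implausible values.
#' @export
tf_sentinels <- function() {
  list(numeric = 999999, date = as.Date("9999-12-31"))
}

clean_missing <- function(dtype, numeric_na = NA_real_) {
  value <- switch(dtype,
    date = as.Date(NA),
    text = NA_character_,
    category = NA_character_,
    numeric_na
  )
  list(value = value, is_sentinel = FALSE, flags = character(0),
       events = list())
}

#' Convert a raw cell to a number
#'
#' Accepts plain decimals with optional sign and thousands separators.
#' Failure substitutes the numeric sentinel and emits `W_TYPE_NUM`; a blank
#' cell is missing, not an error.
#'
#' @param raw Raw cell content (string or number).
#' @param policy Sentinel policy, see [tf_sentinels()].
#' @return A clean-value list (see [cleaning]).
#' @examples
#' convert_numeric("42")$value
#' convert_numeric("abc")$value  # 999999
#' @export
convert_numeric <- function(raw, policy = tf_sentinels()) {
  s <- as.character(raw)
  if (length(s) == 0 || is_blank(s)) return(clean_missing("number"))
  stripped <- gsub(",", "", trimws(s), fixed = TRUE)
  if (grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)$", stripped)) {
    return(list(value = as.numeric(stripped), is_sentinel = FALSE,
                flags = character(0), events = list()))
  }
  list(value = policy$numeric, is_sentinel = TRUE, flags = character(0),
       events = list(new_event("W_TYPE_NUM", raw = s,
                               substituted = as.character(policy$numeric))))
}

MONTH_NAMES <- c(tolower(month.abb), tolower(month.name))

month_number <- function(token) {
  i <- match(tolower(token), MONTH_NAMES)
  if (is.na(i)) return(NA_integer_)
  ((i - 1L) %% 12L) + 1L
}

mk_date <- function(y, m, d) {
  dt <- as.Date(sprintf("%04d-%02d-%02d", y, m, d), format = "%Y-%m-%d")
  dt
}

# Non-anchored regexes for the embedded-date scan; anchored forms are
# derived by wrapping with ^...$ for the direct cascade steps.
DATE_PATTERNS <- list(
  iso = "([0-9]{4})-([0-9]{1,2})-([0-9]{1,2})",
  dmy_name = "([0-9]{1,2})[- ]([A-Za-z]{3,9})[- ]([0-9]{4})",
  my_name = "([A-Za-z]{3,9})[- ]?([0-9]{4})",
  dmy_slash = "([0-9]{1,2})/([0-9]{1,2})/([0-9]{2,4})"
)

interpret_match <- function(which, groups) {
  month_precision <- FALSE
  dayfirst_ambiguous <- FALSE
  dt <- switch(which,
    iso = {
      mk_date(as.integer(groups[1]), as.integer(groups[2]),
              as.integer(groups[3]))
    },
    dmy_name = {
      m <- month_number(groups[2])
      if (is.na(m)) NA else mk_date(as.integer(groups[3]), m,
                                    as.integer(groups[1]))
    },
    my_name = {
      m <- month_number(groups[1])
      month_precision <- TRUE
      if (is.na(m)) NA else mk_date(as.integer(groups[2]), m, 1L)
    },
    dmy_slash = {
      d <- as.integer(groups[1]); m <- as.integer(groups[2])
      y <- as.integer(groups[3])
      if (y < 100) y <- if (y <= 49) 2000L + y else 1900L + y
      dayfirst_ambiguous <- d <= 12 && m <= 12 && d != m
      mk_date(y, m, d)
    }
  )
  if (length(dt) == 0 || is.na(dt)) return(NULL)
  list(date = dt, month_precision = month_precision,
       dayfirst_ambiguous = dayfirst_ambiguous)
}

date_cascade <- function(s, serial_window) {
  # (1) spreadsheet serial number, epoch 1899-12-30
  if (grepl("^[0-9]+(\\.0+)?$", s)) {
    n <- as.numeric(s)
    if (n >= serial_window[["min"]] && n <= serial_window[["max"]]) {
      return(list(date = as.Date(n, origin = "1899-12-30"),
                  month_precision = FALSE, dayfirst_ambiguous = FALSE))
    }
  }
  # (2)-(5) whole-string formats, fixed order
  for (which in names(DATE_PATTERNS)) {
    pat <- paste0("^", DATE_PATTERNS[[which]], "$")
    m <- regmatches(s, regexec(pat, s))[[1]]
    if (length(m) > 0) {
      hit <- interpret_match(which, m[-1])
      if (!is.null(hit)) return(hit)
    }
  }
  # (6) first embedded date substring matching (2)-(5)
  best <- NULL
  best_pos <- Inf
  for (which in names(DATE_PATTERNS)) {
    pos <- regexpr(DATE_PATTERNS[[which]], s)
    if (pos[1] > 0 && pos[1] < best_pos) {
      sub <- regmatches(s, pos)
      m <- regmatches(sub, regexec(paste0("^", DATE_PATTERNS[[which]], "$"),
                                   sub))[[1]]
      hit <- interpret_match(which, m[-1])
      if (!is.null(hit)) {
        best <- hit
        best_pos <- pos[1]
      }
    }
  }
  best
}

#' Parse a date through the multi-format cascade
#'
#' Trackers record dates in many shapes; the cascade tries, in fixed order:
#' spreadsheet serial numbers (window 20000–60000, epoch 1899-12-30), ISO
#' `YYYY-MM-DD`, day–monthname–year (`15-Mar-2022`), monthname–year
#' (`Mar 2022`, completed to day 1 with a `month_precision` flag and an
#' `I_DATE_MONTH_PRECISION` event), numeric `d/m/y` read day-first (an
#' `I_DATE_DAYFIRST` info event marks genuinely ambiguous readings), and
#' finally the first date-shaped substring embedded in a longer string.
#' When every format fails the date sentinel 9999-12-31 is substituted and
#' `W_TYPE_DATE` emitted.
#'
#' @param raw Raw cell content (string or number).
#' @param policy Sentinel policy, see [tf_sentinels()].
#' @param serial_window Named numeric `c(min=, max=)`: the range in which a
#'   bare number is read as a spreadsheet serial date. The floor keeps small
#'   integers (doses, heights) from being misread as dates.
#' @return A clean-value list (see [cleaning]) whose `value` is a `Date`.
#' @examples
#' parse_date("15-Mar-2022")$value
#' parse_date("Mar 2022")$flags
#' parse_date(44635)$value
#' @export
parse_date <- function(raw, policy = tf_sentinels(),
                       serial_window = c(min = 20000, max = 60000)) {
  s <- as.character(raw)
  if (length(s) == 0 || is_blank(s)) return(clean_missing("date"))
  s <- trimws(s)
  hit <- date_cascade(s, serial_window)
  if (is.null(hit)) {
    return(list(value = policy$date, is_sentinel = TRUE,
                flags = character(0),
                events = list(new_event("W_TYPE_DATE", raw = s,
                                        substituted = format(policy$date)))))
  }
  flags <- character(0)
  events <- list()
  if (hit$month_precision) {
    flags <- c(flags, "month_precision")
    events <- c(events, list(new_event("I_DATE_MONTH_PRECISION", raw = s,
                                       substituted = format(hit$date))))
  }
  if (hit$dayfirst_ambiguous) {
    events <- c(events, list(new_event("I_DATE_DAYFIRST", raw = s,
                                       substituted = format(hit$date))))
  }
  list(value = hit$date, is_sentinel = FALSE, flags = flags, events = events)
}

#' Check a number against closed clinical bounds
#'
#' @param value A parsed number.
#' @param bounds Named numeric `c(min=, max=)`; closed interval.
#' @param policy Sentinel policy, see [tf_sentinels()].
#' @return A clean-value list; out-of-range values become the numeric
#'   sentinel with a `W_RANGE` event carrying the raw value.
#' @export
check_range <- function(value, bounds, policy = tf_sentinels()) {
  if (is.na(value)) return(clean_missing("number"))
  if (value >= bounds[["min"]] && value <= bounds[["max"]]) {
    return(list(value = value, is_sentinel = FALSE, flags = character(0),
                events = list()))
  }
  list(value = policy$numeric, is_sentinel = TRUE, flags = character(0),
       events = list(new_event("W_RANGE", raw = as.character(value),
                               substituted = as.character(policy$numeric))))
}

#' Clean a glycated-hemoglobin (HbA1c) value
#'
#' Laboratory reports cap extreme assays as inequalities (`"<7.0"`,
#' `">14"`). The leading inequality symbol is stripped, a
#' `threshold_exceeded` flag retained (event `I_HBA1C_THRESHOLD`), the
#' remainder parsed as a number and range-checked against the configured
#' plausible bounds (0–25 %).
#'
#' @param raw Raw cell content.
#' @param bounds Named numeric `c(min=, max=)` in percent.
#' @param policy Sentinel policy, see [tf_sentinels()].
#' @return A clean-value list (see [cleaning]).
#' @examples
#' clean_hba1c("<7.0")$flags
#' clean_hba1c("30")$value  # 999999
#' @export
clean_hba1c <- function(raw, bounds = c(min = 0, max = 25),
                        policy = tf_sentinels()) {
  s <- as.character(raw)
  if (length(s) == 0 || is_blank(s)) return(clean_missing("number"))
  s <- trimws(s)
  flags <- character(0)
  events <- list()
  if (grepl("^[<>]", s)) {
    flags <- "threshold_exceeded"
    stripped <- trimws(sub("^[<>][[:space:]]*", "", s))
    events <- list(new_event("I_HBA1C_THRESHOLD", raw = s,
                             substituted = stripped))
    s <- stripped
  }
  num <- convert_numeric(s, policy)
  if (num$is_sentinel) {
    num$events[[1]]$raw <- as.character(raw)
    return(list(value = num$value, is_sentinel = TRUE, flags = flags,
                events = c(events, num$events)))
  }
  rng <- check_range(num$value, bounds, policy)
  list(value = rng$value, is_sentinel = rng$is_sentinel, flags = flags,
       events = c(events, rng$events))
}

#' Split a combined blood-pressure string
#'
#' Trackers record blood pressure as a single `"systolic/diastolic"` string,
#' optionally with spaces and a trailing unit (`"120 / 80 mmHg"`). The two
#' components are split and range-checked independently (systolic 50–250,
#' diastolic 30–150 by default). A string not matching the
#' `number / number` grammar substitutes sentinels for both components and
#' emits `W_BP_MALFORMED`.
#'
#' @param raw Raw cell content.
#' @param systolic_bounds,diastolic_bounds Named numeric `c(min=, max=)`.
#' @param policy Sentinel policy, see [tf_sentinels()].
#' @return A list with `systolic` and `diastolic` clean-value lists and a
#'   combined `events` list.
#' @examples
#' split_blood_pressure("120/80")$systolic$value
#' @export
split_blood_pressure <- function(raw,
                                 systolic_bounds = c(min = 50, max = 250),
                                 diastolic_bounds = c(min = 30, max = 150),
                                 policy = tf_sentinels()) {
  s <- as.character(raw)
  if (length(s) == 0 || is_blank(s)) {
    return(list(systolic = clean_missing("number"),
                diastolic = clean_missing("number"), events = list()))
  }
  s <- trimws(s)
  m <- regmatches(s, regexec(
    "^([0-9]{1,3})[[:space:]]*/[[:space:]]*([0-9]{1,3})[[:space:]]*([[:alpha:]. ]*)$", s
  ))[[1]]
  if (length(m) == 0) {
    sentinel <- list(value = policy$numeric, is_sentinel = TRUE,
                     flags = character(0), events = list())
    return(list(
      systolic = sentinel, diastolic = sentinel,
      events = list(new_event("W_BP_MALFORMED", raw = s,
                              substituted = as.character(policy$numeric)))
    ))
  }
  sys <- check_range(as.numeric(m[2]), systolic_bounds, policy)
  dia <- check_range(as.numeric(m[3]), diastolic_bounds, policy)
  list(systolic = sys, diastolic = dia, events = c(sys$events, dia$events))
}

#' Normalize a height to metres
#'
#' Sites record height in centimetres or metres interchangeably; a recorded
#' value above the threshold (50 by default) is read as centimetres and
#' divided by 100, with a `unit_converted` flag and an `I_HEIGHT_CONVERTED`
#' event. The result is then checked against plausible bounds in metres.
#'
#' @param raw Raw cell content (string or number).
#' @param threshold Values strictly above this are centimetres.
#' @param bounds Named numeric `c(min=, max=)` in metres.
#' @param policy Sentinel policy, see [tf_sentinels()].
#' @return A clean-value list (see [cleaning]).
#' @examples
#' normalize_height(170)$value  # 1.7, unit_converted
#' @export
normalize_height <- function(raw, threshold = 50,
                             bounds = c(min = 0.3, max = 2.5),
                             policy = tf_sentinels()) {
  num <- convert_numeric(raw, policy)
  if (is.na(num$value) || num$is_sentinel) return(num)
  flags <- character(0)
  events <- list()
  value <- num$value
  if (value > threshold) {
    value <- value / 100
    flags <- "unit_converted"
    events <- list(new_event("I_HEIGHT_CONVERTED",
                             raw = as.character(raw),
                             substituted = as.character(value)))
  }
  rng <- check_range(value, bounds, policy)
  if (rng$is_sentinel) rng$events[[1]]$raw <- as.character(raw)
  list(value = rng$value, is_sentinel = rng$is_sentinel, flags = flags,
       events = c(events, rng$events))
}

#' Check a categorical value against its allowed set
#'
#' Matching is case-insensitive after header-style normalization; a match
#' returns the canonical casing from the configuration. A non-matching value
#' is *retained as raw text* with a `W_CATEGORY` warning rather than
#' replaced by a sentinel: free-text entries (e.g. locally phrased insulin
#' regimens) are analytically valuable and should reach the analyst, flagged.
#'
#' @param raw Raw cell content.
#' @param allowed Character vector of allowed values (canonical casing).
#' @return A clean-value list (see [cleaning]).
#' @examples
#' check_category("basal-bolus", c("Basal-Bolus", "Premixed"))$value
#' @export
check_category <- function(raw, allowed) {
  s <- as.character(raw)
  if (length(s) == 0 || is_blank(s)) return(clean_missing("category"))
  s <- trimws(s)
  i <- match(normalize_header(s), normalize_header(allowed))
  if (!is.na(i)) {
    return(list(value = allowed[i], is_sentinel = FALSE,
                flags = character(0), events = list()))
  }
  list(value = s, is_sentinel = FALSE, flags = character(0),
       events = list(new_event("W_CATEGORY", raw = s,
                               substituted = NA_character_)))
}

#' Validate a program identifier
#'
#' Program identifiers are a two-letter country code, a two-letter clinic
#' code and a three-digit sequence, e.g. `"VNHC007"`.
#'
#' @param candidate Character string to test.
#' @return A list with `valid` (logical) and `events` (a `W_ID_PATTERN`
#'   event when invalid).
#' @export
validate_identifier <- function(candidate) {
  s <- as.character(candidate)
  ok <- length(s) == 1 && !is.na(s) &&
    grepl("^[A-Z]{2}[A-Z]{2}[0-9]{3}$", s)
  if (ok) {
    list(valid = TRUE, events = list())
  } else {
    list(valid = FALSE,
         events = list(new_event("W_ID_PATTERN", raw = s,
                                 substituted = NA_character_)))
  }
}

#' Parse a program identifier into its components
#'
#' @param x Identifier string such as `"LAVT001"`.
#' @return A list with `country`, `clinic`, `sequence`, `rendered`, or
#'   `NULL` when `x` does not match the pattern.
#' @export
parse_identifier <- function(x) {
  if (!validate_identifier(x)$valid) return(NULL)
  list(country = substr(x, 1, 2), clinic = substr(x, 3, 4),
       sequence = as.integer(substr(x, 5, 7)), rendered = x)
}

#' Render a program identifier
#'
#' @param country,clinic Two-uppercase-letter codes.
#' @param sequence Integer 1–999, zero-padded to width 3.
#' @return The 7-character identifier string.
#' @export
render_identifier <- function(country, clinic, sequence) {
  stopifnot(grepl("^[A-Z]{2}$", country), grepl("^[A-Z]{2}$", clinic))
  if (any(sequence < 1) || any(sequence > 999)) {
    abort("identifier sequence exhausted: must be between 1 and 999")
  }
  sprintf("%s%s%03d", country, clinic, as.integer(sequence))
}

# Clean one field value given its variable definition (one-row tibble).
# Returns list(values = named list of typed scalars, flags = chr, events).
clean_field <- function(raw, vd, config) {
  name <- vd$name
  policy <- config$sentinels
  out_one <- function(cv) {
    list(values = setNames(list(cv$value), name), flags = cv$flags,
         events = cv$events)
  }
  if (!is.na(raw) && identical(trimws(raw), REDACTION_TOKEN)) {
    # already logged at the anonymize stage: keep the token on the key
    # field so the row stays staged (and attributable), missing elsewhere
    if (vd$name %in% c("patient_id", "product_name")) {
      return(list(values = setNames(list(REDACTION_TOKEN), name),
                  flags = character(0), events = list()))
    }
    raw <- NA_character_
  }
  switch(vd$dtype,
    text = {
      if (is_blank(raw)) {
        val <- NA_character_
        events <- list()
      } else {
        val <- trimws(raw)
        events <- if (identical(name, "patient_id")) {
          validate_identifier(val)$events
        } else {
          list()
        }
      }
      list(values = setNames(list(val), name), flags = character(0),
           events = events)
    },
    number = {
      cv <- convert_numeric(raw, policy)
      if (!cv$is_sentinel && !is.na(cv$value) && !is.na(vd$min)) {
        rng <- check_range(cv$value, c(min = vd$min, max = vd$max), policy)
        cv <- list(value = rng$value, is_sentinel = rng$is_sentinel,
                   flags = character(0), events = c(cv$events, rng$events))
      }
      out_one(cv)
    },
    date = out_one(parse_date(raw, policy,
                              config$validation$serial_window)),
    hba1c = out_one(clean_hba1c(raw, c(min = vd$min, max = vd$max), policy)),
    height = out_one(normalize_height(
      raw, config$validation$height_cm_threshold,
      c(min = vd$min, max = vd$max), policy
    )),
    blood_pressure = {
      bp <- split_blood_pressure(raw, config$validation$bp_systolic_bounds,
                                 config$validation$bp_diastolic_bounds,
                                 policy)
      list(
        values = setNames(list(bp$systolic$value, bp$diastolic$value),
                          paste0(name, c("_systolic", "_diastolic"))),
        flags = character(0), events = bp$events
      )
    },
    category = out_one(check_category(raw, vd$allowed[[1]]))
  )
}

#' Clean one extracted record
#'
#' Dispatches every mapped field of a raw record to its dtype-specific
#' cleaner; the record is never dropped, whatever its content. All events
#' are stamped with the record's provenance.
#'
#' @param record A raw record from [extract_records()].
#' @param config A [load_config()] object.
#' @return A list with `entity`, `provenance`, `values` (named list of typed
#'   scalars; blood-pressure fields appear as `*_systolic`/`*_diastolic`),
#'   `flags` (named list, variable -> character flags), `sentinel_fields`
#'   (variables whose value(s) are sentinels) and `events` (list).
#' @export
clean_record <- function(record, config) {
  values <- list()
  flags <- list()
  sentinel_fields <- character(0)
  events <- list()
  for (name in names(record$values)) {
    vd <- var_def(config, record$entity, name)
    if (is.null(vd)) next
    res <- clean_field(record$values[[name]], vd, config)
    values <- c(values, res$values)
    if (length(res$flags) > 0) flags[[name]] <- res$flags
    if (length(res$events) > 0) {
      sent <- any(vapply(res$events, function(e) {
        startsWith(e$code, "W_") && !is.na(e$substituted)
      }, logical(1)))
      if (sent) sentinel_fields <- c(sentinel_fields, name)
      for (e in res$events) {
        e$workbook <- record$provenance$workbook
        e$sheet <- record$provenance$sheet
        e$row <- record$provenance$row
        e$column <- name
        e$clinic <- record$provenance$clinic
        e$period <- record$provenance$period
        events <- c(events, list(e))
      }
    }
  }
  list(entity = record$entity, provenance = record$provenance,
       values = values, flags = flags,
       sentinel_fields = unique(sentinel_fields), events = events)
}
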