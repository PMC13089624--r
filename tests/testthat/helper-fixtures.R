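# Fixture builders shared across the suite. Everything is generated in code
# at test time; no binary fixtures ship with the package.

# A tiny hand-built tracker workbook: 3 rostered patients, one monthly
# sheet. `tweak` lets a test patch cells before writing.
fixture_workbook <- function(dir, name = "tracker_LAVT.xlsx", tweak = NULL) {
  roster <- rbind(
    c("Name", "Patient ID"),
    c("Anna Keo", "LAVT001"),
    c("Bora Lim", "LAVT002"),
    c("Chan Sok", "LAVT003")
  )
  monthly <- rbind(
    c("Name", "HbA1c (%)", "Blood Pressure", "Height (cm)", "Visit Date",
      "Weight (kg)"),
    c("Anna Keo", "7.1", "110/70", "152", "2022-03-15", "48"),
    c("Bora Lim", "<7.0", "120 / 80 mmHg", "1.61", "15-Mar-2022", "55"),
    c("Chan Sok", "8.4", "115/75", "149", "44635", "43.5")
  )
  sheets <- list("Patient List" = roster, "2022-03" = monthly)
  if (!is.null(tweak)) sheets <- tweak(sheets)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, name)
  write_xlsx(sheets, path)
  path
}

# Write a minimal configuration YAML and return its path.
fixture_config_yaml <- function(dir, text) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "config.yaml")
  writeLines(text, path)
  path
}

MINIMAL_CONFIG <- '
variables:
  - {name: hba1c, entity: patient, dtype: hba1c, bounds: {min: 0, max: 25}}
  - {name: patient_id, entity: patient, dtype: text, required: true}
  - {name: visit_date, entity: patient, dtype: date}
synonyms:
  "hba1c (%)": hba1c
  "name": patient_id
  "visit date": visit_date
sentinels:
  numeric: 999999
  date: "9999-12-31"
validation:
  height_cm_threshold: 50
'

# Raw-record constructor for cleaner/loader unit tests.
raw_record <- function(values, entity = "patient", workbook = "wb.xlsx",
                       sheet = "2022-03", row = 1L, clinic = "LAVT",
                       period = "2022-03") {
  list(
    provenance = list(workbook = workbook, sheet = sheet, row = row,
                      clinic = clinic, period = period),
    entity = entity, values = values, unmapped = list()
  )
}

# Shared small generator runs are cached per session to keep the suite fast.
generated_fixture <- local({
  cache <- list()
  function(seed = 7, n_clinics = 2, n_patients = 10, n_months = 4,
           rates = default_corruption_rates()) {
    key <- paste(seed, n_clinics, n_patients, n_months,
                 paste(rates, collapse = ","), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- load_config()
    out <- tempfile("gen_")
    gen <- generate_program(
      generator_config(n_countries = 2, n_clinics = n_clinics,
                       n_patients = n_patients, n_months = n_months,
                       corruption_rates = rates, seed = seed),
      out, cfg
    )
    res <- list(dir = out, gen = gen, cfg = cfg)
    cache[[key]] <<- res
    res
  }
})
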