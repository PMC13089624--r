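# trackerforge

Multi-country diabetes support programs exchange data with partner
hospitals monthly as Excel tracker workbooks: one "Patient List" roster
sheet plus monthly data worksheets, with column names, templates and entry
conventions that differ by site and drift over the years. trackerforge is
an R toolkit that turns those heterogeneous workbooks into database-ready
columnar tables through a pseudonymize → extract → clean → load pipeline
with structured data-quality logging, plus a seeded generator of
realistically messy synthetic trackers for end-to-end testing.

## What it does

* **Pseudonymization first.** Patient names are replaced by structured
  program identifiers — two-letter country code + two-letter clinic code +
  three-digit sequence, e.g. `LAVT001` (pattern
  `^[A-Z]{2}[A-Z]{2}[0-9]{3}$`) — via each workbook's own Patient List.
  A name that matches no roster entry is redacted to `[UNRESOLVED]` and
  logged for manual review; originals are never modified.
* **Synonym-driven extraction.** A YAML configuration declares the
  canonical schema and maps raw header variants onto it (the shipped map
  covers 66 patient and 14 product variables). Header matching is exact
  after normalization — deterministic and auditable, never fuzzy. Data
  boundaries are found from header patterns and `END` marker rows.
* **Cleaning that never drops records.** Unconvertible or clinically
  implausible values become conspicuous sentinels — `999999` for numbers,
  `9999-12-31` for dates — with a coded validation event carrying full cell
  provenance. Dates go through a multi-format cascade (Excel serial
  numbers, ISO, `15-Mar-2022`, `Mar 2022` with a month-precision flag,
  day-first `d/m/y`, dates embedded in text). HbA1c inequality prefixes
  (`<7.0`) strip to a threshold-exceeded flag; `120/80 mmHg` strings split
  into systolic/diastolic; heights above 50 convert from centimetres to
  metres; ranges enforce clinical bounds (age 0–100 y, HbA1c 0–25 %);
  categoricals check against configured allowed values. Blank cells are
  missing values, not errors.
* **Staged columnar output.** Patient and product tables sorted by patient
  and date (with a provenance tie-break), serialized to Apache Parquet;
  all outputs are byte-identical across reruns.
* **Auditing.** Events aggregate into a clinic × period × code matrix with
  per-variable completeness, so data quality is comparable across sites
  and reporting periods.
* **Synthetic program generator.** Seeded multi-clinic workbooks with
  injected, manifest-labelled corruptions (variant date formats, serial
  dates, inequality HbA1c, combined blood pressure, centimetre heights,
  free-text categoricals, typos, blanks, out-of-range values) and template
  drift — insulin-type columns only from 2024 onward.

## Worked example

```r
library(trackerforge)

cfg <- load_config()                       # shipped YAML configuration
base <- tempfile()

gen <- generate_program(
  generator_config(n_countries = 2, n_clinics = 2, n_patients = 10,
                   n_months = 4, seed = 7),
  file.path(base, "raw"), cfg
)
basename(gen$workbooks)
#> [1] "tracker_KHLL.xlsx" "tracker_LARY.xlsx"

anonymize_dir(file.path(base, "raw"), file.path(base, "anon"), cfg)
res <- run_pipeline(file.path(base, "anon"), file.path(base, "staged"), cfg)

res$summary$n_records
#> [1] 104
res$summary$events_by_code[c("W_TYPE_DATE", "I_HEIGHT_CONVERTED")]
#> $W_TYPE_DATE
#> [1] 8
#> $I_HEIGHT_CONVERTED
#> [1] 17

dplyr::select(res$patient, patient_id, record_date, hba1c, height)
#> # A tibble: 40 × 4
#>   patient_id record_date hba1c height
#>   <chr>      <date>      <dbl>  <dbl>
#> 1 KHLL001    2019-07-01   11.5   1.47
#> 2 KHLL001    2024-08-01    9.8   1.31
#> ...
```

104 extracted records (40 patient-month rows, 64 product rows) staged with
every heterogeneous cell either recovered to its typed value or replaced by
a sentinel and logged: the 8 `W_TYPE_DATE` events are unparseable injected
date typos, the 17 `I_HEIGHT_CONVERTED` infos are heights that arrived in
centimetres. The audit report then breaks those counts down by clinic and
reporting period:

```r
rep <- build_audit(res$paths$events, file.path(base, "staged"), cfg)
head(rep$counts, 3)
#> # A tibble: 3 × 4
#>   clinic period  code                       n
#>   <chr>  <chr>   <chr>                  <int>
#> 1 KHLL   2019-07 I_DATE_DAYFIRST            2
#> 2 KHLL   2019-07 I_DATE_MONTH_PRECISION     1
#> 3 KHLL   2019-07 W_TYPE_DATE                4
```

A command-line wrapper with `generate` / `anonymize` / `run` / `audit`
subcommands is installed at
`system.file("cli", "trackerforge", package = "trackerforge")`.

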