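---
title: "Harmonizing multi-site diabetes tracker workbooks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multi-site diabetes tracker workbooks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(trackerforge)
```

## The problem

Multi-country paediatric diabetes support programs exchange patient and
medical-product data with partner hospitals monthly, as Excel tracker
workbooks. Each hospital maintains its own tracker with locally adapted
column names and entry conventions, and templates drift over the years:
columns are renamed, new variables appear (insulin-type fields only exist in
recent templates), dates arrive as spreadsheet serial numbers, `15-Mar-2022`,
`Mar 2022`, or buried inside free text, heights are entered in centimetres
or metres, blood pressure as a single `120/80` string, and HbA1c sometimes
with an inequality prefix (`<7.0`) when an assay was capped.

trackerforge turns those workbooks into database-ready columnar tables
through a three-stage extract–clean–load pipeline, preceded by mandatory
pseudonymization, with every data-quality finding recorded as a structured,
coded validation event. The guiding principles:

* **Never drop, always flag.** A cell that cannot be converted or is
  clinically implausible becomes a conspicuous sentinel (999999 for numbers,
  9999-12-31 for dates) plus a logged event with full cell provenance.
  Records are never discarded by cleaning.
* **Deterministic, auditable mapping.** Header matching is exact after a
  fixed normalization (case-fold, whitespace collapse) against a YAML
  synonym map — no fuzzy matching, which could silently mis-map a column.
* **Reproducibility by construction.** Every stage is a pure function of
  its inputs, the configuration and the seed; reruns produce byte-identical
  XLSX, Parquet, JSON-Lines and report files.

## Pseudonymization

Anonymization happens before all other processing. Each workbook carries a
"Patient List" roster pairing patient names with program identifiers of the
form *country (2 letters) + clinic (2 letters) + sequence (3 digits)*, e.g.
`LAVT001`. `anonymize_workbook()` replaces every whole cell whose normalized
content equals a roster name; a cell in a name-designated column that
matches nothing is replaced by the redaction token `[UNRESOLVED]` and logged
as `W_NAME_UNMATCHED`. The design fails closed: an unmatched (misspelled)
name never survives into the output, at the cost of losing that row's
identity — the log routes it to manual follow-up.

Two deliberate choices here. First, matching is whole-cell only: replacing
substrings inside sentences could corrupt clinical free text, so the
completeness guarantee is enforced by a separate scan instead. Second, the
redaction token is *kept* as the record's `patient_id` during staging (not
nulled), so the row remains in the tables, attributable to its workbook and
sheet, and the roster misspelling is flagged exactly once — at the
anonymization stage, where it happened — rather than again by the cleaner.

## Extraction

`detect_region()` takes the first row in which at least three cells
normalize onto known synonyms as the header (tolerant of decorative title
rows, strict enough to reject prose), and reads data until the first fully
empty row, an `END` marker, or the sheet end. All coordinates are 0-based
with half-open spans, in provenance and logs alike. Unknown headers are
retained on the record and logged (`W_UNMAPPED_COLUMN`) instead of being
silently excluded — silent exclusion loses site-specific observations
without trace, which is precisely the failure mode structured logging is
meant to surface. A sheet's reporting period is parsed from its
`YYYY-MM`-suffixed name; a patient record with no record-date column takes
the first day of that period at staging time.

## Cleaning rules

* **Dates** go through a fixed-order cascade: spreadsheet serial number
  (window 20000–60000, epoch 1899-12-30 — the floor keeps small integers
  such as doses from being misread as dates), ISO, day–monthname–year,
  monthname–year (completed to day 1 with a `month_precision` flag),
  numeric d/m/y read day-first (program countries write day first; a
  genuinely ambiguous reading is logged as info), then the first
  date-shaped substring inside longer text. Total failure substitutes
  9999-12-31 with `W_TYPE_DATE`.
* **HbA1c**: a leading `<` or `>` is stripped and preserved as a
  `threshold_exceeded` flag; the remainder is parsed and range-checked
  against 0–25 %. Stripping precedes the range check so a capped assay is
  judged on its numeric content.
* **Blood pressure**: `number / number` with optional spaces and trailing
  unit text splits into systolic/diastolic, each range-checked (50–250 /
  30–150 mmHg); anything else substitutes sentinels for both components
  under a single `W_BP_MALFORMED` event.
* **Height**: values above 50 are read as centimetres and divided by 100
  (flagged `unit_converted`); the result must fall in 0.3–2.5 m, a
  paediatric-to-adult range.
* **Ranges** are closed intervals — "0–100 years" includes both endpoints.
* **Categoricals** match their configured allowed set case-insensitively
  and take the canonical casing; a non-match is retained as raw text with
  `W_CATEGORY` rather than destroyed, because free-text entries carry
  clinical information.
* **Blanks are missing values**, not errors: no sentinel, no event.
  Missingness and error are different analytical facts and the pipeline
  keeps them distinct.

## Loading and auditing

Cleaned records split into patient and product tables with columns in
canonical-schema order, flags materialized as boolean columns, and rows
sorted by (patient, date) and (clinic, date, product) respectively, with a
(workbook, sheet, row) provenance tie-break that makes the order total and
reruns byte-identical. Tables serialize to Apache Parquet in a local
staging directory — the deployment seam where a cloud uploader would attach.
Provenance columns ride along in the staged tables; they power the audit
joins and the tie-break.

`build_audit()` aggregates events into a clinic × period × code count
matrix and computes per-variable completeness as usable values (neither
missing nor sentinel) over *all* rows of the entity — so a column a site's
older template simply lacks shows up as incompleteness rather than
vanishing from the denominator, making temporal template drift visible.

## The synthetic generator and what passing tests mean

`generate_program()` emulates the program's structure: per-clinic workbooks
(defaults: 7 countries, 42 clinics, 1400 patients, years 2017–2025) with
roster plus monthly patient and product sheets, per-clinic header variants
drawn from the synonym map, title rows, END markers, and insulin-type
columns only from 2024 onward. Corruptions are injected i.i.d. per cell at
configured rates (defaults favour formatting deviations: 30 % centimetre
heights, 15 % variant date formats, 10 % each for serial dates, inequality
HbA1c and spaced blood pressure, a few percent of typos, blanks and
out-of-range values), and every cell is recorded in a ground-truth manifest
labelling its corruption class as recoverable (the cleaner can reconstruct
the true value) or unrecoverable (sentinel or retention plus exactly one
warning).

Each workbook covers 12 sampled months by default rather than the full
108-month range; the month sample is seeded, so both template eras appear.
The generator aims at *structural* realism only: values are plausible but
clinical trajectories are not modelled (no HbA1c dynamics or growth
curves), names are ASCII, and the sheet/marker conventions are
self-consistent stand-ins for conventions that vary in the wild. Passing
the recovery suite therefore demonstrates that the documented cleaning
rules are implemented exactly — not that real trackers contain no
formatting variant outside the generator's inventory.

The test and acceptance runs use desk scale (2–6 clinics, 10–60 patients,
12 months, multiple seeds), which exercises every code path the full scale
would.

## Numerical and edge-case choices

* The numeric sentinel must lie outside every configured bounds interval;
  the loader validates this at startup (which is why the stock-on-hand
  bound tops out below 999999).
* Month-precision dates complete to day 1; the flag, not the day, carries
  the reduced precision.
* Two-digit slash-date years resolve to 2000+ (≤ 49) or 1900+ (≥ 50).
* Duplicate headers mapping to one canonical variable keep the first
  occurrence; the second is unmapped and logged.
* A record lacking its entity key (patient identifier / product name) is
  excluded from staging with a `W_MISSING_KEY` event, so manifest rows
  always equal staged rows plus logged exclusions.

## Limitations

The synonym map ships with a representative schema (66 patient variables,
14 product variables); a deployment would curate it against its own
trackers. Legacy `.xls`, CSV trackers and live spreadsheet APIs are out of
scope, as are imputation, unit inference beyond the height rule, spelling
correction of categoricals, and any cloud upload — the staging directory is
the integration boundary.
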