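cleaned_stub <- function(id, date, workbook = "wb.xlsx", sheet = "s",
                         row = 0L, entity = "patient") {
  key <- if (entity == "patient") "patient_id" else "product_name"
  vals <- setNames(list(id), key)
  if (!is.null(date)) vals$record_date <- as.Date(date)
  if (entity == "product") vals$clinic_code <- "VT"
  list(entity = entity,
       provenance = list(workbook = workbook, sheet = sheet, row = row,
                         clinic = "LAVT", period = NA_character_),
       values = vals, flags = list(), sentinel_fields = character(0),
       events = list())
}

test_that("patient tables sort by patient then date with provenance tie-break", {
  cfg <- load_config()
  recs <- list(
    cleaned_stub("B", "2022-01-01", row = 0L),
    cleaned_stub("B", "2022-02-01", row = 1L),
    cleaned_stub("A", "2022-01-01", row = 2L),
    cleaned_stub("A", "2022-02-01", row = 3L)
  )
  tabs <- assemble_tables(recs, cfg)
  expect_identical(tabs$patient$patient_id, c("A", "A", "B", "B"))
  expect_identical(format(tabs$patient$record_date),
                   c("2022-01-01", "2022-02-01", "2022-01-01", "2022-02-01"))

  dup <- list(
    cleaned_stub("A", "2022-01-01", sheet = "s1", row = 5L),
    cleaned_stub("A", "2022-01-01", sheet = "s1", row = 2L)
  )
  tabs2 <- assemble_tables(dup, cfg)
  expect_identical(nrow(tabs2$patient), 2L)  # both kept
  expect_identical(tabs2$patient$row, c(2L, 5L))
})

test_that("empty input yields empty tables with the full staged schema", {
  cfg <- load_config()
  tabs <- assemble_tables(list(), cfg)
  expect_identical(nrow(tabs$patient), 0L)
  expect_identical(nrow(tabs$product), 0L)
  expect_true(all(c("patient_id", "hba1c", "blood_pressure_systolic",
                    "blood_pressure_diastolic", "hba1c_threshold_exceeded",
                    "height_unit_converted", "visit_date_month_precision")
                  %in% names(tabs$patient)))
  expect_true(all(c("product_name", "stock_on_hand", "expiry_date")
                  %in% names(tabs$product)))
  expect_s3_class(tabs$patient$record_date, "Date")
  expect_type(tabs$patient$hba1c, "double")
})

test_that("records without their entity key are excluded but logged", {
  cfg <- load_config()
  recs <- list(cleaned_stub("A", "2022-01-01"),
               cleaned_stub(NA_character_, "2022-01-01"))
  tabs <- assemble_tables(recs, cfg)
  expect_identical(nrow(tabs$patient), 1L)
  expect_length(tabs$events, 1)
  expect_identical(tabs$events[[1]]$code, "W_MISSING_KEY")
})

test_that("parquet round-trips staged tables exactly, sentinels included", {
  cfg <- load_config()
  recs <- list(cleaned_stub("A", "2022-01-01"), cleaned_stub("B", NULL))
  recs[[1]]$values$hba1c <- 999999
  recs[[2]]$values$visit_date <- as.Date("9999-12-31")
  tabs <- assemble_tables(recs, cfg)
  p1 <- tempfile(fileext = ".parquet")
  write_staged_parquet(tabs$patient, p1)
  back <- arrow::read_parquet(p1)
  expect_equal(as.data.frame(back), as.data.frame(tabs$patient))
  expect_identical(back$hba1c[back$patient_id == "A"], 999999)
  expect_identical(back$visit_date[back$patient_id == "B"],
                   as.Date("9999-12-31"))

  p2 <- tempfile(fileext = ".parquet")
  write_staged_parquet(tabs$patient, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("the pipeline refuses unanonymized input unless overridden", {
  dir_in <- tempfile()
  fixture_workbook(dir_in)
  expect_error(run_pipeline(dir_in, tempfile()), "_ANONYMIZED")
  res <- run_pipeline(dir_in, tempfile(), allow_unanonymized = TRUE)
  expect_identical(res$summary$n_records, 3L)
})

test_that("end-to-end run conserves records and is idempotent", {
  fx <- generated_fixture(seed = 7)
  anon <- tempfile()
  anonymize_dir(fx$dir, anon, fx$cfg)
  out1 <- tempfile(); out2 <- tempfile()
  r1 <- run_pipeline(anon, out1, fx$cfg)
  r2 <- run_pipeline(anon, out2, fx$cfg)
  man_rows <- nrow(unique(fx$gen$manifest[, c("workbook", "sheet", "row")]))
  excluded <- sum(r1$events$code == "W_MISSING_KEY")
  expect_identical(r1$summary$n_patient_rows + r1$summary$n_product_rows +
                     excluded, man_rows)
  for (f in c("patient.parquet", "product.parquet", "events.jsonl",
              "summary.json")) {
    expect_identical(
      readBin(file.path(out1, f), "raw", file.size(file.path(out1, f))),
      readBin(file.path(out2, f), "raw", file.size(file.path(out2, f))),
      info = f
    )
  }
})
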