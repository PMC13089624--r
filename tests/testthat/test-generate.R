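test_that("patient lists carry sequential zero-padded identifiers", {
  roster <- withr::with_seed(7, generate_patient_list(3, "LA", "VT"))
  expect_identical(roster$identifier, c("LAVT001", "LAVT002", "LAVT003"))
  expect_false(anyDuplicated(normalize_header(roster$name)) > 0)

  empty <- withr::with_seed(7, generate_patient_list(0, "VN", "HC"))
  expect_identical(nrow(empty), 0L)
  expect_error(withr::with_seed(7, generate_patient_list(1000, "VN", "HC")),
               "exhausted")

  big <- withr::with_seed(3, generate_patient_list(500, "KH", "PP"))
  expect_length(unique(normalize_header(big$name)), 500)
  expect_true(all(grepl("^KHPP[0-9]{3}$", big$identifier)))
})

test_that("generation is deterministic for a fixed configuration and seed", {
  cfg <- load_config()
  gc <- generator_config(n_countries = 2, n_clinics = 2, n_patients = 10,
                         n_months = 3, seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  g1 <- generate_program(gc, d1, cfg)
  g2 <- generate_program(gc, d2, cfg)
  expect_identical(g1$manifest, g2$manifest)
  for (i in seq_along(g1$workbooks)) {
    expect_identical(
      readBin(g1$workbooks[i], "raw", file.size(g1$workbooks[i])),
      readBin(g2$workbooks[i], "raw", file.size(g2$workbooks[i]))
    )
  }
})

test_that("degenerate corruption rates behave as specified", {
  zero <- setNames(rep(0, length(default_corruption_rates())),
                   names(default_corruption_rates()))
  fx0 <- generated_fixture(seed = 7, rates = zero)
  expect_true(all(fx0$gen$manifest$corruption_class == "none"))

  all_ineq <- zero
  all_ineq["hba1c_inequality"] <- 1
  fx1 <- generated_fixture(seed = 7, rates = all_ineq)
  hb <- fx1$gen$manifest[fx1$gen$manifest$variable == "hba1c", ]
  expect_gt(nrow(hb), 0)
  expect_true(all(grepl("^[<>]", hb$rendered_value)))
})

test_that("rendered cells match what lands in the written workbooks", {
  fx <- generated_fixture(seed = 7)
  man <- fx$gen$manifest
  for (wb_path in fx$gen$workbooks) {
    wb <- read_workbook(wb_path)
    sub <- man[man$workbook == basename(wb_path), ]
    idx <- withr::with_seed(1, sample.int(nrow(sub), min(200, nrow(sub))))
    for (i in idx) {
      e <- sub[i, ]
      cell <- wb[[e$sheet]][e$row + 1, e$col + 1]
      if (e$rendered_value == "") {
        expect_true(is.na(cell) || cell == "")
      } else if (grepl("^-?[0-9.]+$", e$rendered_value)) {
        expect_equal(as.numeric(cell), as.numeric(e$rendered_value))
      } else {
        expect_identical(cell, e$rendered_value)
      }
    }
  }
})

test_that("insulin-type columns appear only from 2024 onward", {
  fx <- generated_fixture(seed = 7, n_months = 8)
  cfg <- fx$cfg
  insulin_vars <- c("insulin_type_basal", "insulin_type_bolus",
                    "insulin_type_premixed")
  seen_pre <- FALSE; seen_post <- FALSE
  for (wb_path in fx$gen$workbooks) {
    wb <- read_workbook(wb_path)
    for (s in names(wb)) {
      period <- regmatches(s, regexpr("[0-9]{4}-[0-9]{2}$", s))
      if (length(period) == 0 || grepl("^Products", s)) next
      region <- detect_region(wb[[s]], cfg)
      mapped <- map_columns(region$headers, cfg)$map
      has_insulin <- any(insulin_vars %in% mapped)
      if (period < "2024-01") {
        expect_false(has_insulin, info = paste(basename(wb_path), s))
        seen_pre <- TRUE
      } else {
        expect_true(has_insulin, info = paste(basename(wb_path), s))
        seen_post <- TRUE
      }
    }
  }
  expect_true(seen_pre && seen_post)
})

test_that("every country appears in at least one clinic assignment", {
  cfg <- load_config()
  gen <- generate_program(
    generator_config(n_countries = 3, n_clinics = 5, n_patients = 5,
                     n_months = 1, seed = 9),
    tempfile(), cfg
  )
  countries <- unique(substr(sub("tracker_", "", basename(gen$workbooks)),
                             1, 2))
  expect_length(countries, 3)
})

test_that("manifest covers exactly the non-empty generated data cells", {
  fx <- generated_fixture(seed = 7)
  man <- fx$gen$manifest
  # one entry per data cell; blank-injected cells are recorded with an
  # empty rendered value and class blank
  expect_false(any(duplicated(man[, c("workbook", "sheet", "row", "col")])))
  expect_true(all(man$rendered_value[man$corruption_class == "blank"] == ""))
  expect_true(all(man$rendered_value[man$corruption_class == "none" &
                                       man$variable != "patient_id"] != ""))
  # recoverability partition is exhaustive
  expect_true(all(man$corruption_class %in%
                    c("none", "date_format_variant", "excel_serial",
                      "embedded_date", "hba1c_inequality", "bp_combined",
                      "height_cm", "typo_unrecoverable", "blank",
                      "out_of_range", "category_freetext")))
})
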