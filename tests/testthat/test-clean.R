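test_that("numeric conversion substitutes the sentinel and flags failures", {
  expect_identical(convert_numeric("42")$value, 42)
  expect_length(convert_numeric("42")$events, 0)
  expect_identical(convert_numeric("1,234.5")$value, 1234.5)

  bad <- convert_numeric("abc")
  expect_identical(bad$value, 999999)
  expect_true(bad$is_sentinel)
  expect_identical(bad$events[[1]]$code, "W_TYPE_NUM")

  blank <- convert_numeric("")
  expect_true(is.na(blank$value))
  expect_false(blank$is_sentinel)
  expect_length(blank$events, 0)
})

test_that("date cascade handles the tracker format inventory", {
  expect_identical(parse_date("15-Mar-2022")$value, as.Date("2022-03-15"))
  expect_identical(parse_date("2022-03-15")$value, as.Date("2022-03-15"))
  expect_identical(parse_date(44635)$value, as.Date("2022-03-15"))
  expect_identical(parse_date("05/03/2022")$value, as.Date("2022-03-05"))

  mp <- parse_date("Mar 2022")
  expect_identical(mp$value, as.Date("2022-03-01"))
  expect_identical(mp$flags, "month_precision")
  expect_identical(mp$events[[1]]$code, "I_DATE_MONTH_PRECISION")

  emb <- parse_date("recorded 15-Mar-2022 at clinic")
  expect_identical(emb$value, as.Date("2022-03-15"))

  bad <- parse_date("not a date")
  expect_identical(bad$value, as.Date("9999-12-31"))
  expect_true(bad$is_sentinel)
  expect_identical(bad$events[[1]]$code, "W_TYPE_DATE")

  # small integers are measurements, not serial dates
  expect_true(parse_date("42")$is_sentinel)
})

test_that("serial dates agree with an independent day-count oracle", {
  # oracle: count days from the spreadsheet epoch through POSIX seconds,
  # independently of Date arithmetic
  withr::with_seed(99, {
    serials <- sample(20000:60000, 50)
    for (s in serials) {
      oracle <- format(
        as.POSIXct(s * 86400, origin = as.POSIXct("1899-12-30", tz = "UTC"),
                   tz = "UTC"),
        "%Y-%m-%d"
      )
      expect_identical(format(parse_date(as.character(s))$value), oracle)
    }
  })
})

test_that("date cascade matches a per-format reconstruction oracle", {
  withr::with_seed(13, {
    dates <- as.Date("2017-01-01") + sample.int(3200, 60)
    for (d in dates) {
      d <- as.Date(d, origin = "1970-01-01")
      expect_identical(parse_date(format(d, "%Y-%m-%d"))$value, d)
      expect_identical(parse_date(format(d, "%d-%b-%Y"))$value, d)
      expect_identical(
        parse_date(sprintf("%02d/%02d/%s", as.integer(format(d, "%d")),
                           as.integer(format(d, "%m")),
                           format(d, "%Y")))$value, d
      )
      serial <- as.integer(round(as.numeric(d - as.Date("1899-12-30"))))
      expect_identical(parse_date(as.character(serial))$value, d)
      first <- as.Date(format(d, "%Y-%m-01"))
      expect_identical(parse_date(format(d, "%b %Y"))$value, first)
    }
  })
})

test_that("HbA1c inequality prefixes strip with a threshold flag", {
  lt <- clean_hba1c("<7.0")
  expect_identical(lt$value, 7)
  expect_identical(lt$flags, "threshold_exceeded")
  expect_identical(lt$events[[1]]$code, "I_HBA1C_THRESHOLD")

  sp <- clean_hba1c("> 14")
  expect_identical(sp$value, 14)
  expect_identical(sp$flags, "threshold_exceeded")

  plain <- clean_hba1c("8.2")
  expect_identical(plain$value, 8.2)
  expect_length(plain$flags, 0)

  out <- clean_hba1c("30")
  expect_identical(out$value, 999999)
  expect_identical(out$events[[1]]$code, "W_RANGE")
})

test_that("blood pressure strings split into range-checked components", {
  bp <- split_blood_pressure("120/80")
  expect_identical(bp$systolic$value, 120)
  expect_identical(bp$diastolic$value, 80)
  expect_length(bp$events, 0)

  spaced <- split_blood_pressure("120 / 80 mmHg")
  expect_identical(spaced$systolic$value, 120)
  expect_identical(spaced$diastolic$value, 80)

  bad <- split_blood_pressure("120-80")
  expect_identical(bad$systolic$value, 999999)
  expect_identical(bad$diastolic$value, 999999)
  expect_identical(bad$events[[1]]$code, "W_BP_MALFORMED")

  high <- split_blood_pressure("400/80")
  expect_identical(high$systolic$value, 999999)
  expect_identical(high$diastolic$value, 80)
  expect_identical(high$events[[1]]$code, "W_RANGE")
})

test_that("heights above the threshold convert from centimetres", {
  cm <- normalize_height(170)
  expect_identical(cm$value, 1.7)
  expect_identical(cm$flags, "unit_converted")
  expect_identical(cm$events[[1]]$code, "I_HEIGHT_CONVERTED")

  m <- normalize_height(1.45)
  expect_identical(m$value, 1.45)
  expect_length(m$flags, 0)

  # 49 is below the threshold, so it reads as metres and fails the bounds
  odd <- normalize_height(49)
  expect_identical(odd$value, 999999)
  expect_identical(odd$events[[1]]$code, "W_RANGE")
})

test_that("range checks use closed clinical bounds", {
  age <- c(min = 0, max = 100)
  expect_identical(check_range(34, age)$value, 34)
  expect_identical(check_range(100, age)$value, 100)  # boundary included
  expect_identical(check_range(0, age)$value, 0)
  over <- check_range(150, age)
  expect_identical(over$value, 999999)
  expect_identical(over$events[[1]]$code, "W_RANGE")
  expect_identical(over$events[[1]]$raw, "150")
})

test_that("tightening bounds never decreases the range-violation count", {
  withr::with_seed(5, {
    values <- runif(200, -50, 150)
    wide <- c(min = 0, max = 100)
    count_range <- function(b) {
      sum(vapply(values, function(v) length(check_range(v, b)$events) > 0,
                 logical(1)))
    }
    n_wide <- count_range(wide)
    for (i in 1:20) {
      lo <- runif(1, 0, 40)
      hi <- runif(1, 60, 100)
      expect_gte(count_range(c(min = lo, max = hi)), n_wide)
    }
  })
})

test_that("categorical values match case-insensitively or are retained", {
  allowed <- c("Basal-Bolus", "Premixed")
  expect_identical(check_category("basal-bolus", allowed)$value,
                   "Basal-Bolus")
  kept <- check_category("unknown regimen text", allowed)
  expect_identical(kept$value, "unknown regimen text")
  expect_false(kept$is_sentinel)
  expect_identical(kept$events[[1]]$code, "W_CATEGORY")
  blank <- check_category("", allowed)
  expect_true(is.na(blank$value))
  expect_length(blank$events, 0)
})

test_that("clean_record dispatches by dtype and stamps provenance", {
  cfg <- load_config()
  rec <- raw_record(list(
    patient_id = "LAVT001", hba1c = "<7.0", blood_pressure = "120/80",
    height = "152", age = "150", visit_date = "garbage", sex = "female",
    notes = ""
  ))
  out <- clean_record(rec, cfg)
  expect_identical(out$values$patient_id, "LAVT001")
  expect_identical(out$values$hba1c, 7)
  expect_identical(out$values$blood_pressure_systolic, 120)
  expect_identical(out$values$height, 1.52)
  expect_identical(out$values$age, 999999)
  expect_identical(out$values$visit_date, as.Date("9999-12-31"))
  expect_identical(out$values$sex, "Female")
  expect_true(is.na(out$values$notes))
  expect_setequal(out$sentinel_fields, c("age", "visit_date"))
  codes <- vapply(out$events, `[[`, character(1), "code")
  expect_true(all(c("W_RANGE", "W_TYPE_DATE", "I_HBA1C_THRESHOLD",
                    "I_HEIGHT_CONVERTED") %in% codes))
  expect_true(all(vapply(out$events, `[[`, character(1), "sheet") ==
                    "2022-03"))
  expect_true(all(vapply(out$events, `[[`, character(1), "clinic") ==
                    "LAVT"))
})
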