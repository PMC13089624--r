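test_that("identifier validation matches an exhaustive structural oracle", {
  expect_true(validate_identifier("VNHC007")$valid)
  bad <- validate_identifier("VNHC07")
  expect_false(bad$valid)
  expect_identical(bad$events[[1]]$code, "W_ID_PATTERN")

  # brute force over all strings of length <= 8 from {A, V, 0, 7}: the
  # acceptance set must equal a structural oracle built without regex
  oracle <- function(s) {
    if (nchar(s) != 7) return(FALSE)
    chars <- strsplit(s, "")[[1]]
    all(chars[1:4] %in% LETTERS) && all(chars[5:7] %in% as.character(0:9))
  }
  alphabet <- c("A", "V", "0", "7")
  for (len in 0:8) {
    strings <- if (len == 0) "" else {
      do.call(paste0, expand.grid(rep(list(alphabet), len),
                                  stringsAsFactors = FALSE))
    }
    got <- vapply(strings, function(s) validate_identifier(s)$valid,
                  logical(1), USE.NAMES = FALSE)
    want <- vapply(strings, oracle, logical(1), USE.NAMES = FALSE)
    expect_identical(got, want, info = paste("length", len))
  }
})

test_that("identifiers render and parse as exact inverses", {
  expect_identical(render_identifier("LA", "VT", 1), "LAVT001")
  p <- parse_identifier("LAVT007")
  expect_identical(p$country, "LA")
  expect_identical(p$clinic, "VT")
  expect_identical(p$sequence, 7L)
  expect_null(parse_identifier("LAVT1"))
  expect_error(render_identifier("LA", "VT", 1000), "exhausted")
})

test_that("lookup builds from the Patient List and rejects conflicts", {
  path <- fixture_workbook(tempfile())
  lookup <- build_lookup(read_workbook(path))
  expect_length(lookup$map, 3)
  expect_identical(unname(lookup$map["anna keo"]), "LAVT001")
  expect_length(lookup$events, 0)

  conflict <- fixture_workbook(tempfile(), tweak = function(sheets) {
    sheets[["Patient List"]] <- rbind(
      c("Name", "Patient ID"),
      c("Anna B", "LAVT001"),
      c("anna  b", "LAVT002")
    )
    sheets
  })
  expect_error(build_lookup(read_workbook(conflict)), "conflicting")

  badid <- fixture_workbook(tempfile(), tweak = function(sheets) {
    sheets[["Patient List"]][2, 2] <- "LAVT1"
    sheets
  })
  lk <- build_lookup(read_workbook(badid))
  expect_length(lk$events, 1)
  expect_identical(lk$events[[1]]$code, "W_ID_PATTERN")
  expect_identical(lk$events[[1]]$raw, "LAVT1")
})

test_that("anonymization replaces every rostered name and redacts the rest", {
  dir_in <- tempfile()
  path <- fixture_workbook(dir_in, tweak = function(sheets) {
    sheets[["2022-03"]][4, 1] <- "Chan Sokk"  # misspelled name
    sheets
  })
  wb <- read_workbook(path)
  lookup <- build_lookup(wb)
  out_dir <- tempfile()
  res <- anonymize_workbook(wb, lookup, out_dir)
  out <- read_workbook(res$path)

  # completeness: no rostered name anywhere, not even as a substring
  all_cells <- tolower(unlist(lapply(out, as.vector)))
  all_cells <- all_cells[!is.na(all_cells)]
  for (nm in c("anna keo", "bora lim", "chan sok")) {
    expect_false(any(grepl(nm, all_cells, fixed = TRUE)), info = nm)
  }
  expect_identical(out[["2022-03"]][2, 1], "LAVT001")
  expect_identical(out[["2022-03"]][4, 1], "[UNRESOLVED]")
  codes <- vapply(res$events, `[[`, character(1), "code")
  expect_identical(codes, "W_NAME_UNMATCHED")
  expect_identical(res$events[[1]]$raw, "Chan Sokk")

  # conservation: sheet count, dimensions and non-name cells untouched
  expect_identical(names(out), names(wb))
  expect_identical(dim(out[["2022-03"]]), dim(wb[["2022-03"]]))
  expect_identical(out[["2022-03"]][, -1], wb[["2022-03"]][, -1])

  # original untouched
  expect_identical(read_workbook(path)[["2022-03"]][2, 1], "Anna Keo")
})

test_that("anonymization refuses to overwrite the input directory", {
  dir_in <- tempfile()
  path <- fixture_workbook(dir_in)
  wb <- read_workbook(path)
  lookup <- build_lookup(wb)
  expect_error(anonymize_workbook(wb, lookup, dir_in), "differ")
})

test_that("anonymizing twice yields byte-identical output", {
  dir_in <- tempfile()
  path <- fixture_workbook(dir_in)
  wb <- read_workbook(path)
  lookup <- build_lookup(wb)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- anonymize_workbook(wb, lookup, d1)$path
  p2 <- anonymize_workbook(wb, lookup, d2)$path
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})
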