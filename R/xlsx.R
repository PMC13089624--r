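#' Minimal deterministic XLSX input/output
#'
#' Tracker workbooks are plain tabular sheets of strings and numbers, so the
#' package works with a deliberately simple in-memory model: a *workbook* is
#' a named list of character matrices, one per sheet, in sheet order. Reading
#' goes through \pkg{readxl} with every cell coerced to text (the cleaning
#' stage owns all typing decisions); writing emits minimal SpreadsheetML
#' (inline strings, numeric `<v>` cells) zipped with fixed file timestamps,
#' so identical workbook models always produce byte-identical `.xlsx` files —
#' the property the pipeline's determinism guarantees rest on.
#'
#' @name xlsx-io
NULL

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# 1-based column index -> spreadsheet letters (1 -> A, 27 -> AA)
col_letter <- function(j) {
  vapply(j, function(n) {
    s <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      n <- (n - 1) %/% 26
    }
    s
  }, character(1))
}

is_numeric_literal <- function(x) {
  grepl("^-?[0-9]+(\\.[0-9]+)?$", x)
}

sheet_xml <- function(mat) {
  header <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main"><sheetData>'
  )
  if (is.null(mat) || length(mat) == 0 || nrow(mat) == 0) {
    return(paste0(header, "</sheetData></worksheet>"))
  }
  nr <- nrow(mat)
  nc <- ncol(mat)
  rows <- character(nr)
  letters_j <- col_letter(seq_len(nc))
  for (i in seq_len(nr)) {
    vals <- mat[i, ]
    keep <- which(!is.na(vals) & nzchar(vals))
    if (length(keep) == 0) {
      rows[i] <- sprintf('<row r="%d"></row>', i)
      next
    }
    refs <- paste0(letters_j[keep], i)
    v <- vals[keep]
    num <- is_numeric_literal(v)
    cells <- character(length(keep))
    cells[num] <- sprintf('<c r="%s"><v>%s</v></c>', refs[num], v[num])
    cells[!num] <- sprintf(
      '<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
      refs[!num], xml_escape(v[!num])
    )
    rows[i] <- sprintf('<row r="%d">%s</row>', i, paste(cells, collapse = ""))
  }
  paste0(header, paste(rows, collapse = ""), "</sheetData></worksheet>")
}

#' Write a workbook model to an XLSX file
#'
#' @param sheets Named list of character matrices (sheet name -> cell grid).
#'   Empty strings and `NA` cells are left blank. Cells that look like plain
#'   decimal numbers are stored as numeric cells, everything else as inline
#'   strings.
#' @param path Output `.xlsx` path; overwritten if present.
#' @return `path`, invisibly.
#' @details Archive entries carry a fixed timestamp (1980-01-01) so the same
#'   `sheets` always serialize to identical bytes.
#' @export
write_xlsx <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) >= 1, !is.null(names(sheets)))
  n <- length(sheets)
  staging <- tempfile("xlsx_")
  dir.create(file.path(staging, "xl", "worksheets"), recursive = TRUE)
  dir.create(file.path(staging, "_rels"), recursive = TRUE)
  dir.create(file.path(staging, "xl", "_rels"), recursive = TRUE)

  put <- function(rel, text) {
    con <- file(file.path(staging, rel), open = "wb")
    writeBin(charToRaw(text), con)
    close(con)
  }

  put("[Content_Types].xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(n)), collapse = ""),
    "</Types>"
  ))
  put(file.path("_rels", ".rels"), paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"
  ))
  put(file.path("xl", "workbook.xml"), paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships"><sheets>',
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  xml_escape(names(sheets)), seq_len(n), seq_len(n)),
          collapse = ""),
    "</sheets></workbook>"
  ))
  put(file.path("xl", "_rels", "workbook.xml.rels"), paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(n), seq_len(n)), collapse = ""),
    "</Relationships>"
  ))
  for (i in seq_len(n)) {
    put(file.path("xl", "worksheets", sprintf("sheet%d.xml", i)),
        sheet_xml(sheets[[i]]))
  }

  files <- list.files(staging, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  files <- sort(files, method = "radix")
  invisible(lapply(
    file.path(staging, files), Sys.setFileTime,
    time = as.POSIXct("1980-01-01 00:00:00", tz = "UTC")
  ))
  if (file.exists(path)) unlink(path)
  zip::zip(normalizePath(path, mustWork = FALSE), files = files,
           root = staging, mode = "mirror", include_directories = FALSE)
  unlink(staging, recursive = TRUE)
  invisible(path)
}

#' Read an XLSX workbook as character matrices
#'
#' All cells are read as text: the cleaning stage, not the spreadsheet
#' engine, decides what is a number, a date, or free text.
#'
#' @param path Path to an `.xlsx` file.
#' @return A named list of character matrices (one per sheet, in file
#'   order), with attribute `path`.
#' @export
read_workbook <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("workbook not found: ", path))
  }
  sheet_names <- readxl::excel_sheets(path)
  sheets <- lapply(sheet_names, function(s) {
    df <- suppressMessages(readxl::read_excel(
      path, sheet = s, col_names = FALSE, col_types = "text",
      .name_repair = "minimal", progress = FALSE
    ))
    if (nrow(df) == 0) {
      matrix(character(0), nrow = 0, ncol = 0)
    } else {
      m <- as.matrix(df)
      dimnames(m) <- NULL
      m
    }
  })
  names(sheets) <- sheet_names
  attr(sheets, "path") <- path
  sheets
}
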