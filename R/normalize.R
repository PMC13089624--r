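#' Normalize a raw column header
#'
#' Column naming conventions vary considerably across hospitals and have
#' drifted over time, so every header comparison in the package goes through
#' a single deterministic normalization: case-folding, conversion of
#' non-breaking spaces to ordinary spaces, trimming, and collapsing of
#' internal whitespace runs to a single space. No fuzzy matching is applied —
#' a header either normalizes onto a known synonym or it does not — which
#' keeps the column mapping auditable.
#'
#' The function is total (any character input is accepted, `NA` maps to `""`)
#' and idempotent.
#'
#' @param raw Character vector of raw header strings.
#' @return Character vector of normalized headers, same length as `raw`.
#' @examples
#' normalize_header("  HbA1c  (%) ")
#' @export
normalize_header <- function(raw) {
  if (length(raw) == 0) return(character(0))
  x <- as.character(raw)
  x[is.na(x)] <- ""
  x <- gsub("\u00a0", " ", x, fixed = TRUE)
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}
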