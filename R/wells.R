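# Well-address helpers for microtiter plates (row letter + 1-based column,
# e.g. "A1" .. "P24" on a 384-well plate).

#' Well names of a plate in row-major order
#'
#' @param rows,cols Plate dimensions (16 x 24 for the 384-well format).
#' @return Character vector of length `rows * cols`, e.g. `"A1"`, `"A2"`, ...
#' @export
well_names <- function(rows = 16L, cols = 24L) {
  rows <- check_count(rows, "rows", min = 1L)
  cols <- check_count(cols, "cols", min = 1L)
  if (rows > 26L) stop_validation("rows > 26 not supported (single-letter rows)")
  as.vector(t(outer(LETTERS[seq_len(rows)], seq_len(cols), paste0)))
}

#' Validate well addresses against a plate format
#'
#' @param wells Character vector like `"A1"`.
#' @param rows,cols Plate dimensions.
#' @return Logical vector, `TRUE` where the address is valid.
#' @export
is_valid_well <- function(wells, rows = 16L, cols = 24L) {
  ok <- grepl("^[A-Z][0-9]+$", wells)
  row_i <- match(substr(wells, 1L, 1L), LETTERS)
  col_i <- suppressWarnings(as.integer(sub("^[A-Z]", "", wells)))
  ok & !is.na(row_i) & row_i <= rows & !is.na(col_i) & col_i >= 1L & col_i <= cols
}
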