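#' Well addresses on a 384-well plate
#'
#' A 384-well plate has 16 rows (`A`--`P`) and 24 columns (`1`--`24`).
#' The canonical string form is the row letter followed by the
#' zero-padded two-digit column, `"A01"` .. `"P24"`, the convention used
#' by plate readers and liquid handlers. `parse_well()` and
#' `format_well()` round-trip through this form.
#'
#' @param well Character vector of well addresses (e.g. `"A01"`, `"p3"`;
#'   case-insensitive, padding optional on input).
#' @param row Integer row index 1--16 (`A` = 1).
#' @param column Integer column index 1--24.
#' @return `parse_well()` returns a tibble with columns `well` (canonical
#'   form), `row` and `column`; `format_well()` returns a character
#'   vector in canonical form.
#' @examples
#' parse_well(c("A01", "p24", "B3"))
#' format_well(1, 1)
#' @export
parse_well <- function(well) {
  well <- toupper(as.character(well))
  ok <- grepl("^[A-Z][0-9]{1,2}$", well)
  if (any(!ok | is.na(well))) {
    bad <- unique(well[!ok | is.na(well)])
    rlang::abort(
      sprintf("Malformed well address(es): %s", paste(utils::head(bad, 5), collapse = ", ")),
      class = "splicescreenr_format_error"
    )
  }
  row <- match(substr(well, 1, 1), LETTERS)
  column <- as.integer(sub("^[A-Z]", "", well))
  out_of_grid <- row > 16L | column < 1L | column > 24L
  if (any(out_of_grid)) {
    bad <- unique(well[out_of_grid])
    rlang::abort(
      sprintf(
        "Well address(es) outside the 384-well grid (A01..P24): %s",
        paste(utils::head(bad, 5), collapse = ", ")
      ),
      class = "splicescreenr_format_error"
    )
  }
  tibble::tibble(well = format_well(row, column), row = row, column = column)
}

#' @rdname parse_well
#' @export
format_well <- function(row, column) {
  stopifnot(all(row >= 1 & row <= 16), all(column >= 1 & column <= 24))
  sprintf("%s%02d", LETTERS[row], as.integer(column))
}

# All 384 canonical addresses in row-major order (A01..A24, B01, ...).
all_wells_384 <- function() {
  as.vector(t(outer(LETTERS[1:16], sprintf("%02d", 1:24), paste0)))
}

well_roles <- c("compound", "dmso_control", "positive_control", "blank", "empty")
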