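#' @importFrom rlang .data .env %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# Delimiter chosen from the file extension: .csv => comma, anything else tab.
delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

read_delim_quiet <- function(path) {
  # read as character and let strtod do the numeric conversion: it is
  # correctly rounded, so full-precision round trips are bit-exact
  raw <- readr::read_delim(
    path,
    delim = delim_for(path), show_col_types = FALSE, progress = FALSE,
    trim_ws = TRUE, col_types = readr::cols(.default = readr::col_character())
  )
  dplyr::mutate(raw, dplyr::across(
    dplyr::everything(), ~ utils::type.convert(.x, as.is = TRUE)))
}

write_delim_quiet <- function(x, path) {
  # serialise doubles at 17 significant digits so write-then-read
  # round-trips reproduce values bit-exactly
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- NA_character_
    out
  }
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.double), fmt))
  readr::write_delim(x, path, delim = delim_for(path), na = "NA")
  invisible(path)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("%s is missing required column(s): %s", what, paste(missing, collapse = ", ")),
      class = "splicescreenr_format_error"
    )
  }
  invisible(df)
}

#' Read a plate layout table
#'
#' A layout maps every addressed well to its role and annotation. It is
#' a delimited-text table (TSV, or CSV by extension) with columns
#' `well`, `role` (one of `compound`, `dmso_control`, `positive_control`,
#' `blank`, `empty`) and optionally `plate_id`, `strain_id`,
#' `compound_id`, `concentration`, `replicate_id`, `library_id`. A layout
#' without `plate_id` is a template applied to every plate it is joined
#' against.
#'
#' @param path Path to a delimited layout file.
#' @return A tibble, one row per well, with parsed/validated addresses
#'   in canonical form.
#' @export
read_plate_layout <- function(path) {
  layout <- read_delim_quiet(path)
  require_columns(layout, c("well", "role"), "layout")
  validate_layout(layout)
}

#' @rdname read_plate_layout
#' @param layout A data frame as described above (validated in place).
#' @export
validate_layout <- function(layout) {
  layout <- tibble::as_tibble(layout)
  require_columns(layout, c("well", "role"), "layout")
  addr <- parse_well(layout$well)
  layout$well <- addr$well
  bad_role <- setdiff(unique(layout$role), well_roles)
  if (length(bad_role) > 0) {
    rlang::abort(
      sprintf("Unknown well role(s): %s", paste(bad_role, collapse = ", ")),
      class = "splicescreenr_layout_error"
    )
  }
  key <- if ("plate_id" %in% names(layout)) paste(layout$plate_id, layout$well) else layout$well
  if (anyDuplicated(key)) {
    rlang::abort(
      sprintf("Duplicate well address in layout: %s", key[duplicated(key)][1]),
      class = "splicescreenr_format_error"
    )
  }
  if (!"compound_id" %in% names(layout)) layout$compound_id <- NA_character_
  if (!"concentration" %in% names(layout)) layout$concentration <- NA_real_
  # role=compound <=> compound_id present; concentration present with compound_id
  is_cmpd <- layout$role == "compound"
  if (any(is_cmpd & is.na(layout$compound_id))) {
    rlang::abort("compound wells must carry a compound_id", class = "splicescreenr_layout_error")
  }
  if (any(!is_cmpd & !is.na(layout$compound_id))) {
    rlang::abort("compound_id on a non-compound well", class = "splicescreenr_layout_error")
  }
  if (any(is_cmpd & is.na(layout$concentration))) {
    rlang::abort("compound wells must carry a concentration", class = "splicescreenr_layout_error")
  }
  layout
}

#' Read end-point plate-reader exports
#'
#' Reads a long-format delimited file with one row per well
#' (`plate_id`, `well`, `od600`, plus optional plate metadata columns
#' `library_id`, `strain_id`, `replicate_id`) and joins every well to
#' its layout record. Rows whose OD fails to parse are retained with
#' `od600 = NA` and reported via a warning, never silently dropped;
#' downstream operations declare their own missing policy.
#'
#' @param path Path to the delimited export.
#' @param layout Layout tibble (from [read_plate_layout()]) covering all
#'   addressed wells, either per plate (`plate_id` column) or as a
#'   template.
#' @return A tibble, one row per well, with layout columns joined:
#'   `plate_id`, `well`, `role`, `strain_id`, `compound_id`,
#'   `concentration`, `replicate_id`, `library_id`, `od600`.
#' @export
read_endpoint_plates <- function(path, layout) {
  raw <- read_delim_quiet(path)
  require_columns(raw, c("plate_id", "well", "od600"), "endpoint plate file")
  layout <- validate_layout(layout)
  raw$well <- parse_well(raw$well)$well
  if (!is.numeric(raw$od600)) {
    parsed <- suppressWarnings(as.numeric(raw$od600))
    n_bad <- sum(is.na(parsed) & !is.na(raw$od600))
    if (n_bad > 0) {
      rlang::warn(sprintf("%d well row(s) had unreadable OD600 values; retained as NA", n_bad))
    }
    raw$od600 <- parsed
  }
  if (anyDuplicated(paste(raw$plate_id, raw$well))) {
    dup <- paste(raw$plate_id, raw$well)[duplicated(paste(raw$plate_id, raw$well))][1]
    rlang::abort(
      sprintf("Duplicate well address within a plate: %s", dup),
      class = "splicescreenr_format_error"
    )
  }
  join_by <- if ("plate_id" %in% names(layout)) c("plate_id", "well") else "well"
  joined <- dplyr::left_join(raw, layout, by = join_by, suffix = c("", ".layout"))
  if (any(is.na(joined$role))) {
    orphan <- joined$well[is.na(joined$role)][1]
    rlang::abort(
      sprintf("Well present in data but absent from layout: %s", orphan),
      class = "splicescreenr_layout_error"
    )
  }
  meta_cols <- intersect(
    c("plate_id", "well", "role", "strain_id", "compound_id", "concentration",
      "replicate_id", "library_id"),
    names(joined)
  )
  dplyr::select(joined, dplyr::all_of(meta_cols), "od600") |>
    dplyr::arrange(.data$plate_id, .data$well)
}

#' Read a wide 16 x 24 plate matrix
#'
#' Convenience dialect for exports laid out as the physical plate: a
#' header row of column numbers 1..24 and sixteen rows labelled A..P.
#' Returns the same long form as [read_endpoint_plates()] expects.
#'
#' @param path Path to the wide-format file.
#' @param plate_id Plate identifier to assign.
#' @return A tibble with `plate_id`, `well`, `od600`.
#' @export
read_endpoint_plate_wide <- function(path, plate_id) {
  wide <- read_delim_quiet(path)
  rows <- toupper(as.character(wide[[1]]))
  if (!all(rows %in% LETTERS[1:16])) {
    rlang::abort("wide plate file must have row labels A..P in the first column",
      class = "splicescreenr_format_error")
  }
  vals <- as.matrix(wide[, -1])
  cols <- as.integer(sub("^[Xx]", "", colnames(vals)))
  tibble::tibble(
    plate_id = plate_id,
    well = format_well(rep(match(rows, LETTERS), each = ncol(vals)), rep(cols, times = nrow(vals))),
    od600 = as.numeric(t(vals))
  ) |> dplyr::arrange(.data$well)
}

#' Read kinetic plate-reader exports
#'
#' Long-format file with one row per well per measurement cycle:
#' `plate_id`, `well`, `time_min` (or `cycle` with a stated cadence),
#' `od600`, `fluorescence`. Per-well series must be strictly increasing
#' in time in file order; the measurement cadence is inferred as the
#' median inter-cycle spacing and recorded, and wells with gaps larger
#' than 1.5 cadences are flagged (`gapped`), retained.
#'
#' @inheritParams read_endpoint_plates
#' @return A tibble with layout columns joined plus `cycle`, `time_min`,
#'   `od600`, `fluorescence`, `gapped`; the inferred cadence (minutes)
#'   is attached as attribute `cadence_min`.
#' @export
read_kinetic_traces <- function(path, layout) {
  raw <- read_delim_quiet(path)
  require_columns(raw, c("plate_id", "well", "time_min", "od600", "fluorescence"),
    "kinetic trace file")
  layout <- validate_layout(layout)
  raw$well <- parse_well(raw$well)$well
  raw <- dplyr::group_by(raw, .data$plate_id, .data$well)
  mono <- dplyr::summarise(raw, ok = all(diff(.data$time_min) > 0), .groups = "drop")
  if (any(!mono$ok)) {
    bad <- mono[!mono$ok, ][1, ]
    rlang::abort(
      sprintf("Non-monotone time series within well %s of plate %s", bad$well, bad$plate_id),
      class = "splicescreenr_format_error"
    )
  }
  cadence <- stats::median(unlist(dplyr::group_map(raw, ~ diff(.x$time_min))))
  out <- raw |>
    dplyr::mutate(
      cycle = as.integer(round(.data$time_min / .env$cadence)) + 1L,
      gapped = any(diff(.data$time_min) > 1.5 * .env$cadence)
    ) |>
    dplyr::ungroup()
  join_by <- if ("plate_id" %in% names(layout)) c("plate_id", "well") else "well"
  joined <- dplyr::left_join(out, layout, by = join_by, suffix = c("", ".layout"))
  if (any(is.na(joined$role))) {
    orphan <- joined$well[is.na(joined$role)][1]
    rlang::abort(
      sprintf("Well present in data but absent from layout: %s", orphan),
      class = "splicescreenr_layout_error"
    )
  }
  meta_cols <- intersect(
    c("plate_id", "well", "role", "strain_id", "reporter", "compound_id",
      "concentration", "replicate_id", "library_id"),
    names(joined)
  )
  res <- dplyr::select(
    joined, dplyr::all_of(meta_cols),
    "cycle", "time_min", "od600", "fluorescence", "gapped"
  ) |>
    dplyr::arrange(.data$plate_id, .data$well, .data$time_min)
  attr(res, "cadence_min") <- cadence
  res
}

#' Write screen tables to delimited text
#'
#' `write_endpoint_plates()` and `write_kinetic_traces()` write the long
#' canonical forms so that a write-then-read round trip reproduces
#' values exactly (numbers are serialised at full round-trip precision).
#'
#' @param plates,traces Tibbles in the long canonical forms produced by
#'   the readers or the simulator.
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return The path, invisibly.
#' @export
write_endpoint_plates <- function(plates, path) {
  write_delim_quiet(
    dplyr::arrange(tibble::as_tibble(plates), .data$plate_id, .data$well), path
  )
}

#' @rdname write_endpoint_plates
#' @export
write_kinetic_traces <- function(traces, path) {
  write_delim_quiet(
    dplyr::arrange(tibble::as_tibble(traces), .data$plate_id, .data$well, .data$time_min), path
  )
}
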