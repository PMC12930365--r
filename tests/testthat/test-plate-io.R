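test_that("well addresses round-trip through the canonical string form", {
  all384 <- all_wells_384()
  expect_length(all384, 384)
  parsed <- parse_well(all384)
  expect_identical(parsed$well, all384)
  expect_identical(format_well(parsed$row, parsed$column), all384)
  # lenient input forms normalise
  expect_identical(parse_well(c("a1", "P24"))$well, c("A01", "P24"))
})

test_that("addresses outside the 384-well grid are format errors", {
  expect_error(parse_well("Q01"), class = "splicescreenr_format_error")
  expect_error(parse_well("A25"), class = "splicescreenr_format_error")
  expect_error(parse_well("A00"), class = "splicescreenr_format_error")
  expect_error(parse_well("11"), class = "splicescreenr_format_error")
})

test_that("endpoint reader joins every well to its layout record", {
  sc <- mini_scenario()
  camp <- simulate_screen(sc, kinetic_compounds = character(0))
  plate <- dplyr::filter(camp$endpoint, plate_id == camp$endpoint$plate_id[1])
  data_file <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(plate[, c("plate_id", "well", "od600")], data_file)
  layout <- plate[, c("well", "role", "strain_id", "compound_id", "concentration",
    "replicate_id", "library_id")]
  got <- read_endpoint_plates(data_file, layout)
  expect_equal(nrow(got), 384)
  # layout join is total: every well carries a role
  expect_false(any(is.na(got$role)))
  expect_equal(got$od600, plate$od600[order(plate$well)])
  expect_equal(sum(got$role == "dmso_control"), 16)
  expect_equal(sum(got$role == "positive_control"), 16)
})

test_that("duplicate addresses and orphan wells are rejected", {
  layout <- tibble::tibble(well = c("A01", "A02"), role = "dmso_control")
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    plate_id = "P1", well = c("A01", "A01"), od600 = c(0.5, 0.6)), f)
  expect_error(read_endpoint_plates(f, layout), class = "splicescreenr_format_error")
  readr::write_tsv(tibble::tibble(
    plate_id = "P1", well = c("A01", "B05"), od600 = c(0.5, 0.6)), f)
  expect_error(read_endpoint_plates(f, layout), class = "splicescreenr_layout_error")
})

test_that("unreadable OD rows are reported and retained as missing", {
  layout <- tibble::tibble(well = c("A01", "A02"), role = "dmso_control")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,well,od600", "P1,A01,0.5", "P1,A02,oops"), f)
  expect_warning(got <- read_endpoint_plates(f, layout), "unreadable")
  expect_equal(nrow(got), 2)
  expect_true(is.na(got$od600[got$well == "A02"]))
})

test_that("the wide 16x24 dialect reads to the same long form", {
  od <- matrix(round(stats::runif(384), 4), nrow = 16,
    dimnames = list(LETTERS[1:16], 1:24))
  f <- withr::local_tempfile(fileext = ".tsv")
  wide <- cbind(data.frame(row = rownames(od)), as.data.frame(od))
  readr::write_tsv(wide, f)
  got <- read_endpoint_plate_wide(f, plate_id = "W1")
  expect_equal(nrow(got), 384)
  expect_equal(got$od600[got$well == "B03"], od["B", "3"])
  expect_equal(got$od600[got$well == "P24"], od["P", "24"])
})

test_that("kinetic traces read back sorted with cadence and gap flags", {
  layout <- tibble::tibble(well = c("A01", "A02"), role = c("compound", "dmso_control"),
    compound_id = c("C1", NA), concentration = c(10, NA))
  t_full <- seq(0, 90, by = 15)
  t_gap <- setdiff(t_full, 45) # missing one cycle
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::bind_rows(
    tibble::tibble(plate_id = "K1", well = "A01", time_min = t_full,
      od600 = 0.1, fluorescence = 5),
    tibble::tibble(plate_id = "K1", well = "A02", time_min = t_gap,
      od600 = 0.1, fluorescence = 5)), f)
  got <- read_kinetic_traces(f, layout)
  expect_equal(attr(got, "cadence_min"), 15)
  expect_false(any(got$gapped[got$well == "A01"]))
  expect_true(all(got$gapped[got$well == "A02"]))
  expect_equal(nrow(got), length(t_full) + length(t_gap)) # gapped well retained
  # non-monotone time within a well is a format error
  readr::write_tsv(tibble::tibble(plate_id = "K1", well = "A01",
    time_min = c(0, 15, 10), od600 = 0.1, fluorescence = 5), f)
  expect_error(read_kinetic_traces(f, layout), class = "splicescreenr_format_error")
})

test_that("write-then-read round trip reproduces simulated values exactly", {
  sc <- mini_scenario()
  camp <- simulate_screen(sc)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_endpoint_plates(camp$endpoint, f)
  layout <- dplyr::distinct(camp$endpoint, plate_id, well, role,
    strain_id, compound_id, concentration, replicate_id, library_id)
  got <- read_endpoint_plates(f, layout)
  orig <- dplyr::arrange(camp$endpoint, plate_id, well)
  expect_identical(got$od600, orig$od600)
  expect_identical(got$compound_id, orig$compound_id)

  fk <- withr::local_tempfile(fileext = ".tsv")
  kin <- camp$kinetics
  write_kinetic_traces(kin, fk)
  klayout <- dplyr::distinct(kin, plate_id, well, role, strain_id, reporter,
    compound_id, concentration, replicate_id)
  gotk <- read_kinetic_traces(fk, klayout)
  origk <- dplyr::arrange(kin, plate_id, well, time_min)
  expect_identical(gotk$fluorescence, origk$fluorescence)
  expect_identical(gotk$od600, origk$od600)
})

test_that("screen reports are deterministic files, one QC row per plate", {
  sc <- mini_scenario()
  report <- run_pipeline(sc)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_screen_report(report, d1)
  write_screen_report(report, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      info = f)
  }
  qc <- readr::read_tsv(file.path(d1, "qc.tsv"), show_col_types = FALSE)
  expect_equal(nrow(qc), dplyr::n_distinct(sc$strains) * sc$libraries$n_replicates)
  # empty hit table still yields a valid header-only file
  empty <- list(primary = dplyr::filter(report$primary, FALSE))
  d3 <- withr::local_tempdir()
  write_screen_report(empty, d3)
  got <- readr::read_tsv(file.path(d3, "primary.tsv"), show_col_types = FALSE)
  expect_equal(nrow(got), 0)
  expect_true("compound_id" %in% names(got))
})
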