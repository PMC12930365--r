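# Minimal kinetic tibble: one compound well and one DMSO well per
# (plate, reporter); fluorescence passed in directly.
make_traces <- function(f_compound, f_dmso, reporter = "SPLOOF",
                        strain = "Hs-Hsh155", replicate = 1L,
                        plate_id = paste0("K_", strain, "_", reporter, "_R", replicate)) {
  n <- length(f_compound)
  dplyr::bind_rows(
    tibble::tibble(plate_id = plate_id, well = "A01", role = "compound",
      strain_id = strain, reporter = reporter, compound_id = "C1",
      concentration = 10, replicate_id = replicate, cycle = seq_len(n),
      time_min = (seq_len(n) - 1) * 15, od600 = 0.5, fluorescence = f_compound),
    tibble::tibble(plate_id = plate_id, well = "B01", role = "dmso_control",
      strain_id = strain, reporter = reporter, compound_id = NA_character_,
      concentration = NA_real_, replicate_id = replicate, cycle = seq_len(n),
      time_min = (seq_len(n) - 1) * 15, od600 = 0.5, fluorescence = f_dmso))
}

test_that("per-cycle DMSO normalisation is an exact ratio", {
  f <- c(10, 20, 30, 40)
  ident <- normalize_timecourse(make_traces(f, f))
  expect_equal(ident$f_norm, rep(1, 4))
  doubled <- normalize_timecourse(make_traces(2 * f, f))
  expect_equal(doubled$f_norm, rep(2, 4))
  # cycles with a zero DMSO mean are undefined, not infinite
  zero <- normalize_timecourse(make_traces(f, c(5, 0, 5, 5)))
  expect_true(is.na(zero$f_norm[2]))
  expect_equal(zero$f_norm[c(1, 3, 4)], f[c(1, 3, 4)] / 5)
  # no aligned DMSO trace at all is an error
  lone <- dplyr::filter(make_traces(f, f), role == "compound")
  expect_error(normalize_timecourse(lone),
    class = "splicescreenr_normalization_error")
})

test_that("persistence windows obey strict inequalities and the run-length rule", {
  # ratios exactly 1.0 never qualify
  at_one <- persistence_windows(sploof = rep(1.0, 20), splif = rep(0.5, 20))
  expect_equal(nrow(at_one), 0)
  # 9 consecutive qualifying cycles: window found but does not qualify
  q9 <- c(rep(FALSE, 3), rep(TRUE, 9), rep(FALSE, 8))
  w9 <- persistence_windows(sploof = ifelse(q9, 1.5, 0.9),
    splif = ifelse(q9, 0.5, 1.2), min_cycles = 10)
  expect_equal(w9$n_cycles, 9)
  expect_false(any(w9$qualifies))
  # extending to 10 flips the decision, and the window spans 2.5 h
  q10 <- c(rep(FALSE, 3), rep(TRUE, 10), rep(FALSE, 7))
  w10 <- persistence_windows(sploof = ifelse(q10, 1.5, 0.9),
    splif = ifelse(q10, 0.5, 1.2), min_cycles = 10, cadence_min = 15)
  expect_true(w10$qualifies[1])
  expect_equal(w10$duration_h[1], 2.5)
  # undefined cycles break runs rather than bridging them
  sploof <- rep(1.5, 21); splif <- rep(0.5, 21)
  sploof[11] <- NA
  broken <- persistence_windows(sploof, splif, min_cycles = 10)
  expect_equal(broken$n_cycles, c(10, 10))
  expect_equal(broken$start_cycle, c(1, 12))
})

test_that("detector agrees with brute-force window enumeration", {
  withr::local_seed(41)
  for (i in 1:300) {
    n <- sample(1:100, 1)
    k <- sample(1:15, 1)
    sploof <- stats::runif(n, 0.5, 1.5)
    splif <- stats::runif(n, 0.5, 1.5)
    q <- sploof > 1 & splif < 1
    w <- persistence_windows(sploof, splif, min_cycles = k)
    expect_identical(any(w$qualifies), brute_force_has_run(q, k))
    runs <- brute_force_runs(q)
    expect_equal(nrow(w), length(runs))
    if (length(runs) > 0) {
      expect_equal(w$start_cycle, vapply(runs, `[[`, numeric(1), "start"))
      expect_equal(w$n_cycles, vapply(runs, `[[`, numeric(1), "len"))
    }
  }
})

test_that("increasing min_cycles never adds a hit; cycle labels drive decisions", {
  withr::local_seed(43)
  for (i in 1:50) {
    n <- 60
    sploof <- stats::runif(n, 0.6, 1.6)
    splif <- stats::runif(n, 0.6, 1.6)
    q10 <- any(persistence_windows(sploof, splif, min_cycles = 10)$qualifies)
    q12 <- any(persistence_windows(sploof, splif, min_cycles = 12)$qualifies)
    expect_true(!q12 || q10)
    # resampling the time labels (cadence) changes reported duration only
    w15 <- persistence_windows(sploof, splif, min_cycles = 10, cadence_min = 15)
    w30 <- persistence_windows(sploof, splif, min_cycles = 10, cadence_min = 30)
    expect_identical(w15$qualifies, w30$qualifies)
    expect_equal(w30$duration_h, 2 * w15$duration_h)
  }
})

test_that("replicate reproducibility is required per background", {
  good <- c(rep(0.9, 5), rep(1.5, 12), rep(0.8, 10))   # SPLOOF with a 12-cycle rise
  flat <- rep(0.95, 27)                                 # never above 1
  lowf <- rep(0.5, 27)                                  # SPLIF suppressed throughout
  both <- dplyr::bind_rows(
    make_traces(good, rep(1, 27), "SPLOOF", replicate = 1L),
    make_traces(lowf, rep(1, 27), "SPLIF", replicate = 1L),
    make_traces(good, rep(1, 27), "SPLOOF", replicate = 2L),
    make_traces(lowf, rep(1, 27), "SPLIF", replicate = 2L))
  calls <- detect_persistent_modulation(normalize_timecourse(both))
  hits <- call_secondary_hits(calls)
  expect_true(hits$is_hit)
  expect_equal(hits$strains_hit, "Hs-Hsh155")
  # one failing replicate sinks the background
  one_off <- dplyr::bind_rows(
    make_traces(good, rep(1, 27), "SPLOOF", replicate = 1L),
    make_traces(lowf, rep(1, 27), "SPLIF", replicate = 1L),
    make_traces(flat, rep(1, 27), "SPLOOF", replicate = 2L),
    make_traces(lowf, rep(1, 27), "SPLIF", replicate = 2L))
  calls2 <- detect_persistent_modulation(normalize_timecourse(one_off))
  hits2 <- call_secondary_hits(calls2)
  expect_false(hits2$is_hit)
  # a missing replicate leaves the compound incomplete, excluded
  single <- dplyr::bind_rows(
    make_traces(good, rep(1, 27), "SPLOOF", replicate = 1L),
    make_traces(lowf, rep(1, 27), "SPLIF", replicate = 1L))
  hits3 <- call_secondary_hits(detect_persistent_modulation(normalize_timecourse(single)))
  expect_false(hits3$is_hit)
  expect_equal(hits3$status, "incomplete")
})

test_that("a wholly missing reporter is an alignment error", {
  sploof_only <- make_traces(rep(1.5, 20), rep(1, 20), "SPLOOF")
  expect_error(
    detect_persistent_modulation(normalize_timecourse(sploof_only)),
    class = "splicescreenr_alignment_error")
})

test_that("planted modulators classify as hits and growth-only toxics never do", {
  sc <- mini_scenario(seed = 53)
  camp <- simulate_screen(sc) # kinetics default to planted actives + toxics
  norm <- normalize_timecourse(camp$kinetics)
  calls <- detect_persistent_modulation(norm)
  hits <- call_secondary_hits(calls)
  mods <- camp$truth$compound_id[camp$truth$type == "modulator"]
  tox <- camp$truth$compound_id[camp$truth$type == "toxic"]
  expect_true(all(mods %in% hits$compound_id[hits$is_hit]))
  expect_false(any(tox %in% hits$compound_id[hits$is_hit]))
  # oracle loop: per compound/background/replicate decisions match a
  # brute-force rescan of the qualifying sequence
  wide <- tidyr::pivot_wider(
    dplyr::select(norm, compound_id, strain_id, replicate_id, reporter, cycle, f_norm),
    names_from = reporter, values_from = f_norm)
  for (i in seq_len(nrow(calls))) {
    df <- wide[wide$compound_id == calls$compound_id[i] &
      wide$strain_id == calls$strain_id[i] &
      wide$replicate_id == calls$replicate_id[i], ]
    df <- df[order(df$cycle), ]
    q <- !is.na(df$SPLOOF) & !is.na(df$SPLIF) & df$SPLOOF > 1 & df$SPLIF < 1
    expect_identical(calls$is_hit_replicate[i], brute_force_has_run(q, 10L))
  }
})
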