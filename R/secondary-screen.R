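#' Per-cycle DMSO normalisation of kinetic traces
#'
#' Each compound trace is divided, cycle by cycle, by the mean
#' fluorescence of the DMSO wells matched on plate (hence strain,
#' reporter and replicate under the standard kinetic plate design).
#' Cycles where the DMSO mean is zero are marked undefined (`NA`) and
#' later break persistence runs rather than being bridged.
#'
#' @param traces Long kinetic tibble ([read_kinetic_traces()] /
#'   [simulate_kinetic_traces()] schema) containing both compound and
#'   `dmso_control` wells.
#' @param by Grouping columns identifying a normalisation stratum;
#'   defaults to plate-matched DMSO wells.
#' @return A tibble of compound-well rows with `dmso_mean` and
#'   `f_norm = fluorescence / dmso_mean` added.
#' @export
normalize_timecourse <- function(traces, by = c("plate_id", "cycle")) {
  dmso <- traces |>
    dplyr::filter(.data$role == "dmso_control") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(dmso_mean = mean(.data$fluorescence, na.rm = TRUE),
      .groups = "drop")
  compound <- dplyr::filter(traces, .data$role == "compound")
  strata <- setdiff(by, "cycle")
  missing_dmso <- dplyr::anti_join(
    dplyr::distinct(compound, dplyr::across(dplyr::all_of(strata))),
    dplyr::distinct(dmso, dplyr::across(dplyr::all_of(strata))),
    by = strata)
  if (nrow(missing_dmso) > 0) {
    rlang::abort(
      sprintf("no aligned DMSO trace for: %s",
        paste(do.call(paste, missing_dmso[1, , drop = FALSE]), collapse = " ")),
      class = "splicescreenr_normalization_error")
  }
  compound |>
    dplyr::left_join(dmso, by = by) |>
    dplyr::mutate(f_norm = dplyr::if_else(
      !is.na(.data$dmso_mean) & .data$dmso_mean > 0,
      .data$fluorescence / .data$dmso_mean, NA_real_))
}

#' Maximal runs of persistent dual-reporter modulation
#'
#' Low-level detector on two aligned normalised series: a cycle
#' qualifies when the SPLOOF ratio is strictly above 1 and the SPLIF
#' ratio strictly below 1 at that same cycle. Returns all maximal runs
#' of consecutive qualifying cycles; undefined (`NA`) cycles break runs.
#'
#' @param sploof,splif Normalised fluorescence ratios on the same cycle
#'   grid.
#' @param cycles Cycle indices (default `seq_along(sploof)`).
#' @param min_cycles Minimum run length to qualify (default 10).
#' @param cadence_min Measurement cadence used to report window
#'   durations in hours (default 15 min, so 10 cycles span 2.5 h).
#' @return A tibble of maximal qualifying runs: `start_cycle`,
#'   `end_cycle`, `n_cycles`, `duration_h`, `qualifies`.
#' @examples
#' persistence_windows(sploof = rep(1.4, 12), splif = rep(0.6, 12))
#' @export
persistence_windows <- function(sploof, splif, cycles = seq_along(sploof),
                                min_cycles = 10L, cadence_min = 15) {
  if (length(sploof) != length(splif) || length(sploof) != length(cycles)) {
    rlang::abort("sploof and splif series must share one cycle grid",
      class = "splicescreenr_alignment_error")
  }
  q <- !is.na(sploof) & !is.na(splif) & sploof > 1.0 & splif < 1.0
  r <- rle(q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(
    start_cycle = cycles[starts[keep]],
    end_cycle = cycles[ends[keep]],
    n_cycles = r$lengths[keep],
    duration_h = r$lengths[keep] * cadence_min / 60,
    qualifies = r$lengths[keep] >= min_cycles)
}

#' Detect persistent splicing modulation per replicate
#'
#' Pairs the SPLOOF and SPLIF normalised traces of the same compound,
#' genetic background and replicate (the reporters live in different
#' wells of sibling strains) and applies the consecutive-cycle
#' persistence rule: a replicate qualifies when some run of at least
#' `min_cycles` consecutive cycles has SPLOOF ratio > 1.0 and SPLIF
#' ratio < 1.0 simultaneously. At the standard 15-min cadence the
#' default 10-cycle minimum spans 2.5 h.
#'
#' @param normalized Output of [normalize_timecourse()], containing a
#'   `reporter` column with both `"SPLIF"` and `"SPLOOF"` rows.
#' @param min_cycles Minimum consecutive qualifying cycles (default 10).
#' @param cadence_min Measurement cadence in minutes.
#' @return A tibble with one row per compound x strain x replicate:
#'   `is_hit_replicate`, `n_windows`, `best_window` cycles, and a
#'   `windows` list-column of maximal qualifying runs.
#' @export
detect_persistent_modulation <- function(normalized, min_cycles = 10L,
                                         cadence_min = 15) {
  wide <- normalized |>
    dplyr::select("compound_id", "strain_id", "replicate_id", "reporter",
      "cycle", "f_norm") |>
    tidyr::pivot_wider(names_from = "reporter", values_from = "f_norm")
  if (!all(c("SPLIF", "SPLOOF") %in% names(wide))) {
    rlang::abort("normalized traces must include both SPLIF and SPLOOF reporters",
      class = "splicescreenr_alignment_error")
  }
  wide |>
    dplyr::arrange(.data$cycle) |>
    dplyr::group_by(.data$compound_id, .data$strain_id, .data$replicate_id) |>
    dplyr::group_modify(function(df, key) {
      if (all(is.na(df$SPLIF)) || all(is.na(df$SPLOOF))) {
        rlang::abort(
          sprintf("no aligned SPLIF/SPLOOF pair for compound %s in %s",
            key$compound_id, key$strain_id),
          class = "splicescreenr_alignment_error")
      }
      w <- persistence_windows(df$SPLOOF, df$SPLIF, cycles = df$cycle,
        min_cycles = min_cycles, cadence_min = cadence_min)
      qual <- dplyr::filter(w, .data$qualifies)
      tibble::tibble(
        is_hit_replicate = nrow(qual) > 0,
        n_windows = nrow(qual),
        best_start = if (nrow(qual)) qual$start_cycle[which.max(qual$n_cycles)] else NA_integer_,
        best_n_cycles = if (nrow(qual)) max(qual$n_cycles) else NA_integer_,
        best_duration_h = if (nrow(qual)) max(qual$duration_h) else NA_real_,
        windows = list(qual))
    }) |>
    dplyr::ungroup()
}

#' Call secondary splicing-modulator hits
#'
#' A compound is a secondary hit in a genetic background when every
#' configured replicate independently contains a qualifying persistence
#' window there (windows need not overlap across replicates); it is an
#' overall hit when it qualifies in at least one background. Compounds
#' with fewer replicates than required are excluded with a reason.
#'
#' @param calls Per-replicate tibble from
#'   [detect_persistent_modulation()].
#' @param n_replicates_required Replicates that must each qualify
#'   (default 2, duplicate screens).
#' @return A tibble with one row per compound: `is_hit`, `strains_hit`
#'   (semicolon-joined backgrounds), `n_strains_hit`, `status`, and a
#'   `provenance` list-column of per-background replicate windows.
#' @export
call_secondary_hits <- function(calls, n_replicates_required = 2L) {
  per_bg <- calls |>
    dplyr::group_by(.data$compound_id, .data$strain_id) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      all_qualify = all(.data$is_hit_replicate),
      complete = dplyr::n() >= n_replicates_required,
      windows = list(.data$windows),
      .groups = "drop") |>
    dplyr::mutate(bg_hit = .data$complete & .data$all_qualify)
  hits <- per_bg |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      is_hit = any(.data$bg_hit),
      strains_hit = paste(sort(.data$strain_id[.data$bg_hit]), collapse = ";"),
      n_strains_hit = sum(.data$bg_hit),
      status = dplyr::if_else(all(.data$complete), "ok", "incomplete"),
      .groups = "drop")
  provenance <- per_bg |>
    dplyr::select("compound_id", "strain_id", "n_replicates", "bg_hit") |>
    tidyr::nest(provenance = c("strain_id", "n_replicates", "bg_hit"))
  dplyr::left_join(hits, provenance, by = "compound_id")
}
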