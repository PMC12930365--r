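#' Pipeline configuration
#'
#' Collects every threshold the two-tier pipeline applies, so a report
#' is auditable against its configuration. All thresholds default to
#' the screening campaign's canonical values.
#'
#' @param inhibition_threshold Primary hit threshold on growth
#'   inhibition (default 0.30).
#' @param z_prime_min Plate QC gate on Z' (default 0.5).
#' @param min_cycles Secondary persistence rule, consecutive qualifying
#'   cycles (default 10).
#' @param n_secondary_replicates Replicates that must each qualify in
#'   the secondary screen (default 2).
#' @param policy Primary [replicate_policy()].
#' @param strains The four configured strain identifiers.
#' @param seed Integer seed forwarded to simulation.
#' @return A `screen_config` list.
#' @export
screen_config <- function(inhibition_threshold = 0.30, z_prime_min = 0.5,
                          min_cycles = 10L, n_secondary_replicates = 2L,
                          policy = replicate_policy(),
                          strains = default_strains(), seed = 1L) {
  stopifnot(inhibition_threshold >= 0, inhibition_threshold <= 1,
    z_prime_min <= 1, min_cycles >= 1)
  structure(
    list(inhibition_threshold = inhibition_threshold, z_prime_min = z_prime_min,
      min_cycles = as.integer(min_cycles),
      n_secondary_replicates = as.integer(n_secondary_replicates),
      policy = policy, strains = strains, seed = as.integer(seed)),
    class = c("screen_config", "list"))
}

#' Run the two-tier screening pipeline
#'
#' Chains the stages on provided or simulated data: plate QC gate ->
#' DMSO growth normalisation -> primary hit calling and selectivity
#' partition -> per-cycle DMSO normalisation of kinetic traces ->
#' persistence classification -> secondary hit calling -> rule-of-five
#' and PAINS triage. When given a [simulation_scenario()], end-point
#' plates are simulated for the whole campaign and kinetic traces only
#' for the primary hits (the cherry-picked secondary tier), and planted
#' ground truth is joined into a recovery summary. When `kinetics` is
#' absent from provided data, the secondary stage is skipped with a
#' notice and a primary-only report is returned.
#'
#' @param x A [simulation_scenario()], or a list with tibbles
#'   `endpoint` (required), `kinetics`, `compounds`, `truth` (optional).
#' @param config A [screen_config()].
#' @return A `screen_report` list of tibbles: `qc`, `inhibition`,
#'   `primary`, `selectivity`, `secondary_calls`, `secondary`,
#'   `triage`, `recovery` (when truth is available), plus the applied
#'   `config` and a `log` of thresholds and stage notices.
#' @export
run_pipeline <- function(x, config = screen_config()) {
  log <- c(
    sprintf("inhibition_threshold=%g", config$inhibition_threshold),
    sprintf("z_prime_min=%g", config$z_prime_min),
    sprintf("min_cycles=%d", config$min_cycles),
    sprintf("n_secondary_replicates=%d", config$n_secondary_replicates),
    sprintf("policy=%s n_total=%d", config$policy$mode, config$policy$n_total))
  simulated <- inherits(x, "simulation_scenario")
  if (simulated) {
    scenario <- x
    campaign <- simulate_screen(scenario, kinetic_compounds = character(0))
    endpoint <- campaign$endpoint
    compounds <- campaign$compounds
    truth <- campaign$truth
    log <- c(log, sprintf("simulated campaign: %d compounds, seed=%d",
      nrow(compounds), scenario$noise$seed))
  } else {
    endpoint <- x$endpoint
    compounds <- x$compounds
    truth <- x$truth
    if (is.null(endpoint)) {
      rlang::abort("run_pipeline needs end-point plates", class = "splicescreenr_config_error")
    }
  }

  gate <- qc_gate(endpoint, z_threshold = config$z_prime_min)
  if (nrow(gate$qc) > sum(gate$qc$pass)) {
    log <- c(log, sprintf("qc: excluded %d plate(s) below Z' %.2f",
      sum(!gate$qc$pass), config$z_prime_min))
  }
  inhibition <- normalize_growth(gate$passing)
  primary <- call_primary_hits(inhibition, policy = config$policy,
    threshold = config$inhibition_threshold)
  selectivity <- selectivity_partition(primary, strains = config$strains)
  primary_hit_ids <- sort(unique(primary$compound_id[primary$is_hit]))
  log <- c(log, sprintf("primary: %d hit compound(s)", length(primary_hit_ids)))

  kinetics <- if (simulated) {
    if (length(primary_hit_ids) > 0) {
      simulate_kinetic_traces(scenario, primary_hit_ids)
    } else NULL
  } else {
    x$kinetics
  }

  if (is.null(kinetics) || nrow(kinetics) == 0) {
    log <- c(log, "secondary: skipped (no kinetic traces)")
    secondary_calls <- NULL
    secondary <- NULL
  } else {
    normalized <- normalize_timecourse(kinetics)
    normalized <- dplyr::semi_join(normalized,
      tibble::tibble(compound_id = primary_hit_ids), by = "compound_id")
    secondary_calls <- detect_persistent_modulation(normalized,
      min_cycles = config$min_cycles)
    secondary <- call_secondary_hits(secondary_calls,
      n_replicates_required = config$n_secondary_replicates)
    log <- c(log, sprintf("secondary: %d hit compound(s)", sum(secondary$is_hit)))
  }

  triage <- if (!is.null(compounds) &&
    all(c("mw", "logp", "hbd", "hba") %in% names(compounds))) {
    hit_compounds <- dplyr::filter(compounds, .data$compound_id %in% primary_hit_ids)
    rule_of_five(hit_compounds) |> pains_screen()
  } else NULL

  recovery <- if (!is.null(truth)) {
    truth |>
      dplyr::mutate(
        primary_hit = .data$compound_id %in% primary_hit_ids,
        secondary_hit = .data$compound_id %in%
          (if (is.null(secondary)) character(0) else
            secondary$compound_id[secondary$is_hit])) |>
      dplyr::group_by(.data$type) |>
      dplyr::summarise(n = dplyr::n(), n_primary = sum(.data$primary_hit),
        n_secondary = sum(.data$secondary_hit), .groups = "drop")
  } else NULL

  structure(
    list(qc = gate$qc, inhibition = inhibition, primary = primary,
      selectivity = selectivity, secondary_calls = secondary_calls,
      secondary = secondary, triage = triage, recovery = recovery,
      config = config, log = log),
    class = c("screen_report", "list"))
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Two-tier screen report\n")
  for (line in x$log) cat(" -", line, "\n")
  if (!is.null(x$recovery)) {
    cat("Planted-compound recovery:\n")
    print(as.data.frame(x$recovery), row.names = FALSE)
  }
  invisible(x)
}

# Drops list-columns and fixes column order so reports are
# byte-reproducible across runs of the same inputs.
flatten_report_table <- function(df) {
  df |>
    dplyr::select(dplyr::where(~ !is.list(.x))) |>
    dplyr::arrange(dplyr::across(dplyr::everything()))
}

#' Write a screen report bundle to disk
#'
#' Writes each report table as a machine-readable TSV with a
#' deterministic column and row order, plus a short human-readable
#' summary (`summary.txt`) including per-plate Z' and the applied
#' thresholds. Regenerating from the same inputs produces
#' byte-identical files.
#'
#' @param report A `screen_report` from [run_pipeline()], or a named
#'   list of tibbles.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- report[vapply(report, is.data.frame, logical(1))]
  for (name in names(tables)) {
    readr::write_tsv(flatten_report_table(tables[[name]]),
      file.path(dir, paste0(name, ".tsv")), na = "NA", progress = FALSE)
  }
  summary_lines <- c("Two-tier screen report", "======================")
  if (!is.null(report$log)) summary_lines <- c(summary_lines, report$log)
  if (!is.null(report$qc)) {
    summary_lines <- c(summary_lines, "",
      sprintf("plates: %d (%d passing QC)", nrow(report$qc), sum(report$qc$pass)))
  }
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
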