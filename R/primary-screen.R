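#' Replicate policy for primary hit calling
#'
#' `full_replicate` screens every compound `n_total` times;
#' `cherry_pick` screens once, selects qualifiers showing at least
#' `qualifier_threshold` inhibition in the first pass, and rescreens
#' only those to a total of `n_total` replicates (the workflow used for
#' large libraries).
#'
#' @param mode `"full_replicate"` or `"cherry_pick"`.
#' @param n_total Total replicates a hit decision requires (>= 2 for
#'   cherry-pick).
#' @param qualifier_threshold First-pass inhibition fraction selecting
#'   compounds for rescreening (default 0.30).
#' @return A `replicate_policy` list.
#' @export
replicate_policy <- function(mode = c("full_replicate", "cherry_pick"),
                             n_total = 3L, qualifier_threshold = 0.30) {
  mode <- match.arg(mode)
  n_total <- as.integer(n_total)
  stopifnot(n_total >= 1)
  if (mode == "cherry_pick" && n_total < 2) {
    rlang::abort("cherry_pick requires n_total >= 2", class = "splicescreenr_policy_error")
  }
  structure(list(mode = mode, n_total = n_total,
    qualifier_threshold = qualifier_threshold),
    class = c("replicate_policy", "list"))
}

#' DMSO-normalised growth inhibition
#'
#' For every compound well, `growth_fraction = OD / mean(DMSO OD on the
#' same plate)` and `inhibition = 1 - growth_fraction`. Normalisation is
#' per plate, since controls are dispensed on every plate. Negative
#' inhibition (growth stimulation) is retained — it is informative but
#' can never qualify as a hit.
#'
#' @param plates Long end-point tibble; should contain only QC-passing
#'   plates (see [qc_gate()]).
#' @return A tibble with one row per compound well: `compound_id`,
#'   `strain_id`, `replicate_id`, `plate_id`, `well`, `od600`,
#'   `dmso_mean`, `growth_fraction`, `inhibition`.
#' @export
normalize_growth <- function(plates) {
  dmso <- plates |>
    dplyr::filter(.data$role == "dmso_control") |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(dmso_mean = mean(.data$od600, na.rm = TRUE),
      n_dmso = sum(!is.na(.data$od600)), .groups = "drop")
  bad <- dmso$plate_id[dmso$n_dmso < 1 | dmso$dmso_mean <= 0 | is.na(dmso$dmso_mean)]
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("plate(s) without a usable DMSO reference: %s", paste(bad, collapse = ", ")),
      class = "splicescreenr_plate_error")
  }
  plates |>
    dplyr::filter(.data$role == "compound") |>
    dplyr::left_join(dplyr::select(dmso, "plate_id", "dmso_mean"), by = "plate_id") |>
    dplyr::mutate(
      growth_fraction = .data$od600 / .data$dmso_mean,
      inhibition = 1 - .data$growth_fraction) |>
    dplyr::select("compound_id", "strain_id", "replicate_id", "plate_id", "well",
      "od600", "dmso_mean", "growth_fraction", "inhibition")
}

#' Call primary growth-inhibition hits
#'
#' A compound is a hit in a strain when it consistently inhibits growth:
#' ALL of its `n_total` replicate inhibitions must reach the threshold
#' (inclusive, "at least 30%"). Under `cherry_pick`, qualifiers are
#' selected from the first-pass replicate at the policy's qualifier
#' threshold before the consistency rule is applied to all replicates.
#' An alternative mean-over-replicates rule is available via
#' `rule = "mean"`. Compounds with fewer replicates than the policy
#' demands are flagged incomplete and excluded with a reason.
#'
#' @param records Inhibition tibble from [normalize_growth()].
#' @param policy A [replicate_policy()].
#' @param threshold Inhibition fraction defining a hit (default 0.30).
#' @param rule `"all"` (every replicate >= threshold; default) or
#'   `"mean"` (replicate mean >= threshold).
#' @return A tibble with one row per compound x strain:
#'   `compound_id`, `strain_id`, `n_replicates`, `inhibitions`
#'   (list-column), `min_inhibition`, `mean_inhibition`, `is_hit`,
#'   `status` (`"ok"`, `"incomplete"`, `"not_qualified"`), `rationale`.
#' @export
call_primary_hits <- function(records, policy = replicate_policy(),
                              threshold = 0.30, rule = c("all", "mean")) {
  rule <- match.arg(rule)
  grouped <- records |>
    dplyr::filter(!is.na(.data$inhibition)) |>
    dplyr::arrange(.data$compound_id, .data$strain_id, .data$replicate_id) |>
    dplyr::group_by(.data$compound_id, .data$strain_id) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      inhibitions = list(.data$inhibition),
      first_pass = .data$inhibition[which.min(.data$replicate_id)],
      min_inhibition = min(.data$inhibition),
      mean_inhibition = mean(.data$inhibition),
      .groups = "drop")
  grouped |>
    dplyr::mutate(
      qualified = policy$mode != "cherry_pick" |
        .data$first_pass >= policy$qualifier_threshold,
      complete = dplyr::if_else(.data$qualified,
        .data$n_replicates >= policy$n_total, TRUE),
      meets = if (rule == "all") .data$min_inhibition >= threshold else
        .data$mean_inhibition >= threshold,
      is_hit = .data$qualified & .data$complete & .data$meets,
      status = dplyr::case_when(
        !.data$qualified ~ "not_qualified",
        !.data$complete ~ "incomplete",
        TRUE ~ "ok"),
      rationale = dplyr::case_when(
        status == "not_qualified" ~ sprintf(
          "first-pass inhibition %.3f below qualifier %.2f",
          .data$first_pass, policy$qualifier_threshold),
        status == "incomplete" ~ sprintf(
          "%d of %d required replicates", .data$n_replicates, policy$n_total),
        is_hit ~ sprintf("all %d replicate inhibitions >= %.2f",
          .data$n_replicates, threshold),
        TRUE ~ sprintf("min replicate inhibition %.3f < %.2f",
          .data$min_inhibition, threshold))) |>
    dplyr::select(-"qualified", -"complete", -"meets", -"first_pass")
}

#' Strain-selectivity partition of primary hits
#'
#' Partitions hit compounds into the 15 nonempty strain-subset classes
#' (the Venn-diagram cells over four strains). The all-four class
#' collects compounds with general growth-inhibitory properties; the
#' singleton classes are strain-selective.
#'
#' @param hits Hit tibble from [call_primary_hits()].
#' @param strains Character vector of the 4 configured strain ids.
#' @return A tibble of all 15 classes: `strains` (semicolon-joined,
#'   sorted), `n_strains`, `n_compounds`, `compounds` (list-column).
#'   Class counts sum to the number of hit compounds.
#' @export
selectivity_partition <- function(hits, strains = default_strains()) {
  stopifnot(length(strains) == 4)
  hit_rows <- dplyr::filter(hits, .data$is_hit)
  unknown <- setdiff(unique(hit_rows$strain_id), strains)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown strain id(s): %s", paste(unknown, collapse = ", ")),
      class = "splicescreenr_config_error")
  }
  profile <- hit_rows |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      strains = paste(sort(unique(.data$strain_id)), collapse = ";"),
      .groups = "drop")
  # all 15 nonempty subsets, in size order then lexicographic
  subsets <- unlist(lapply(1:4, function(k) {
    utils::combn(sort(strains), k, FUN = paste, collapse = ";", simplify = FALSE)
  }))
  counts <- profile |>
    dplyr::group_by(.data$strains) |>
    dplyr::summarise(n_compounds = dplyr::n(),
      compounds = list(sort(.data$compound_id)), .groups = "drop")
  tibble::tibble(strains = subsets) |>
    dplyr::left_join(counts, by = "strains") |>
    dplyr::mutate(
      n_strains = lengths(strsplit(.data$strains, ";")),
      n_compounds = dplyr::coalesce(.data$n_compounds, 0L),
      compounds = purrr::map(.data$compounds, ~ .x %||% character(0))) |>
    dplyr::select("strains", "n_strains", "n_compounds", "compounds")
}
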