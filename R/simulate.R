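#' Hill dose-response inhibition fraction
#'
#' `I(c) = max_inhibition * c^hill / (ec50^hill + c^hill)`, the
#' fractional inhibition exerted by a compound at concentration `c`.
#'
#' @param conc Concentration(s), same units as `ec50`; must be >= 0.
#' @param dr A [dose_response_params()] set.
#' @return Numeric vector of inhibition fractions in `[0, max_inhibition]`.
#' @export
hill_inhibition <- function(conc, dr) {
  if (any(conc < 0)) {
    rlang::abort("negative concentration", class = "splicescreenr_domain_error")
  }
  ifelse(conc == 0, 0,
    dr$max_inhibition * conc^dr$hill / (dr$ec50^dr$hill + conc^dr$hill))
}

# Logistic OD at hours t_h for effective rate r_eff (per hour); lagged
# and continuous at t = lag. r_eff near zero freezes OD at the inoculum.
logistic_od <- function(gp, r_eff, t_h) {
  a <- (gp$k_cap - gp$od0) / gp$od0
  tau <- pmax(0, t_h - gp$lag)
  if (r_eff < 1e-12) return(rep(gp$od0, length(t_h)))
  gp$k_cap / (1 + a * exp(-r_eff * tau))
}

# Cumulative biomass integral (OD * hours) of the lagged logistic from
# 0 to t_h, closed form.
biomass_integral <- function(gp, r_eff, t_h) {
  a <- (gp$k_cap - gp$od0) / gp$od0
  tau <- pmax(0, t_h - gp$lag)
  pre <- gp$od0 * pmin(t_h, gp$lag)
  if (r_eff < 1e-12) return(gp$od0 * t_h)
  pre + (gp$k_cap / r_eff) * log((a + exp(r_eff * tau)) / (a + 1))
}

#' Noiseless growth curve under drug
#'
#' Logistic growth with a lag phase, the drug acting multiplicatively on
#' the growth rate: `r_eff = r * (1 - I(conc))` with the Hill inhibition
#' `I` of [hill_inhibition()]. Full inhibition (`I = 1`) freezes the
#' culture at the inoculum density, which is how saturating phleomycin
#' wells behave.
#'
#' @inheritParams hill_inhibition
#' @param gp A [growth_params()] set.
#' @param times Measurement times in minutes, increasing.
#' @return Absorbance (OD600) at each time, noiseless.
#' @examples
#' gp <- growth_params()
#' growth_curve(gp, dose_response_params(ec50 = 1), conc = 0, times = c(0, 720, 1440))
#' @export
growth_curve <- function(gp, dr, conc, times) {
  stopifnot(!is.unsorted(times))
  inh <- hill_inhibition(conc, dr)
  logistic_od(gp, gp$r * (1 - inh), times / 60)
}

# Drug effect on splicing: s(conc) = s0 * (1 - Hill(conc)), where the
# Hill term's depth defaults to 1 (full splicing shutdown at saturation)
# and can be overridden per compound via splice_dr.
splicing_efficiency <- function(rp, conc, splice_dr = NULL) {
  dr <- splice_dr %||%
    dose_response_params(ec50 = rp$splice_ec50, hill = rp$splice_hill, max_inhibition = 1)
  rp$splicing_efficiency_0 * (1 - hill_inhibition(conc, dr))
}

#' Noiseless reporter fluorescence trace
#'
#' Fluorescent protein production is proportional to instantaneous
#' biomass times the fraction of reporter transcripts in the productive
#' form: the spliced fraction `s` for the splicing-in-frame (SPLIF)
#' reporter, the unspliced fraction plus leak `1 - s + leak` for the
#' splicing-out-of-frame (SPLOOF) reporter. Measured fluorescence is the
#' accumulated product delayed by fluorophore maturation, plus a small
#' constant autofluorescence per unit biomass.
#'
#' @inheritParams growth_curve
#' @param rp A [reporter_params()] set.
#' @param reporter `"SPLIF"` or `"SPLOOF"`.
#' @param splice_dr Optional [dose_response_params()] overriding the
#'   reporter-level Hill parameters of the drug effect on splicing
#'   (used by the simulator for per-compound splicing effects).
#' @return Fluorescence (arbitrary units) at each time, noiseless.
#' @export
reporter_trace <- function(gp, dr, rp, conc, reporter = c("SPLIF", "SPLOOF"),
                           times, splice_dr = NULL) {
  reporter <- match.arg(reporter)
  stopifnot(!is.unsorted(times))
  inh <- hill_inhibition(conc, dr)
  r_eff <- gp$r * (1 - inh)
  s <- splicing_efficiency(rp, conc, splice_dr)
  frac <- if (reporter == "SPLIF") s else (1 - s + rp$leak_sploof)
  yield <- if (reporter == "SPLIF") rp$yield_splif else rp$yield_sploof
  t_h <- times / 60
  b <- biomass_integral(gp, r_eff, pmax(0, t_h - rp$maturation_delay / 60))
  yield * frac * b + rp$autofluor * logistic_od(gp, r_eff, t_h)
}

# ---- campaign assembly ----------------------------------------------------

# Compound table for a scenario: planted modulators/toxics occupy the
# first identifiers, the rest of each library is inert.
scenario_compounds <- function(scenario) {
  planted <- unique(c(planted_ids(scenario$planted_modulators),
    planted_ids(scenario$planted_toxics)))
  lib <- scenario$libraries
  n_total <- sum(lib$n_compounds)
  inert_ids <- sprintf("CPD%04d", seq_len(n_total - length(planted)))
  ids <- c(planted, inert_ids)
  tibble::tibble(
    compound_id = ids,
    library_id = rep(lib$library_id, lib$n_compounds),
    concentration = rep(lib$concentration, lib$n_compounds)
  )
}

# Per (compound, strain) growth inhibition fraction at the screening
# concentration; inert pairs have inhibition 0.
planted_inhibition <- function(scenario, compound_id, strain_id, conc) {
  inh <- numeric(length(compound_id))
  mods <- scenario$planted_modulators
  if (nrow(mods) > 0) {
    key <- paste(compound_id, strain_id)
    mkey <- paste(mods$compound_id, mods$strain_id)
    idx <- match(key, mkey)
    hit <- !is.na(idx)
    if (any(hit)) {
      m <- mods[idx[hit], ]
      inh[hit] <- m$max_inhibition * conc[hit]^m$hill / (m$ec50^m$hill + conc[hit]^m$hill)
    }
  }
  tox <- scenario$planted_toxics
  if (nrow(tox) > 0) {
    idx <- match(compound_id, tox$compound_id)
    hit <- !is.na(idx)
    if (any(hit)) {
      tt <- tox[idx[hit], ]
      inh[hit] <- tt$max_inhibition * conc[hit]^tt$hill / (tt$ec50^tt$hill + conc[hit]^tt$hill)
    }
  }
  inh
}

# Per-compound splicing-effect dose-response (depth splice_max) in a
# given strain; NULL rows (no planted splicing effect) give s = s0.
planted_splice_fraction <- function(scenario, compound_id, strain_id, conc) {
  eff <- numeric(length(compound_id)) # Hill term of the splicing effect
  mods <- scenario$planted_modulators
  if (nrow(mods) > 0) {
    key <- paste(compound_id, strain_id)
    mkey <- paste(mods$compound_id, mods$strain_id)
    idx <- match(key, mkey)
    hit <- !is.na(idx)
    if (any(hit)) {
      m <- mods[idx[hit], ]
      eff[hit] <- m$splice_max * conc[hit]^m$splice_hill /
        (m$splice_ec50^m$splice_hill + conc[hit]^m$splice_hill)
    }
  }
  eff
}

# Standard 384-well screening layout: compounds in columns 1..22 (352
# slots, row-major), DMSO controls in column 23, positive controls in
# column 24. Unused compound slots are empty wells.
campaign_layout <- function(scenario) {
  compounds <- scenario_compounds(scenario)
  slots <- format_well(rep(1:16, times = 22), rep(1:22, each = 16))
  n <- nrow(compounds)
  if (n > length(slots)) {
    rlang::abort("default layout supports at most 352 compounds per plate",
      class = "splicescreenr_scenario_error")
  }
  tibble::tibble(
    well = c(slots, format_well(1:16, 23L), format_well(1:16, 24L)),
    role = c(rep("compound", n), rep("empty", length(slots) - n),
      rep("dmso_control", 16L), rep("positive_control", 16L)),
    compound_id = c(compounds$compound_id, rep(NA_character_, length(slots) - n + 32L)),
    concentration = c(compounds$concentration, rep(NA_real_, length(slots) - n + 32L)),
    library_id = compounds$library_id[1]
  )
}

#' Simulate a complete screening campaign
#'
#' Generates end-point 384-well plates for every strain and replicate of
#' the scenario (with DMSO and saturating positive-control wells),
#' kinetic dual-reporter traces for a compound subset, a compound
#' annotation table with simulated descriptors, and the ground-truth
#' table of planted effects for recovery scoring. Deterministic given
#' the scenario seed: each plate draws from a seed derived from the
#' master seed, so any plate subset is reproducible.
#'
#' @param scenario A [simulation_scenario()].
#' @param kinetic_compounds Compound identifiers to simulate kinetic
#'   traces for; defaults to all planted modulators and toxics. Use
#'   [simulate_kinetic_traces()] directly to target another set (e.g.
#'   the primary-hit list, as [run_pipeline()] does).
#' @return A list of class `screen_campaign` with tibbles `endpoint`,
#'   `kinetics`, `compounds`, `truth`.
#' @export
simulate_screen <- function(scenario, kinetic_compounds = NULL) {
  layout <- campaign_layout(scenario)
  grid <- tidyr::expand_grid(
    strain_id = scenario$strains,
    replicate_id = seq_len(max(scenario$libraries$n_replicates))
  )
  gp <- scenario$growth
  np <- scenario$noise
  end_t <- scenario$duration_h * 60
  plates <- purrr::pmap_dfr(grid, function(strain_id, replicate_id) {
    idx <- match(strain_id, scenario$strains) * 1000L + replicate_id
    plate <- layout
    plate$plate_id <- sprintf("%s_%s_R%d", plate$library_id[1], strain_id, replicate_id)
    plate$strain_id <- strain_id
    plate$replicate_id <- replicate_id
    inh <- rep(0, nrow(plate))
    is_cmpd <- plate$role == "compound"
    inh[is_cmpd] <- planted_inhibition(
      scenario, plate$compound_id[is_cmpd], strain_id, plate$concentration[is_cmpd])
    mean_od <- vapply(
      gp$r * (1 - inh), function(re) logistic_od(gp, re, end_t / 60), numeric(1))
    mean_od[plate$role == "positive_control"] <- gp$od0 # saturating inhibitor
    mean_od[plate$role %in% c("empty", "blank")] <- 0
    local_seed(derive_seed(np$seed, idx))
    plate$od600 <- pmax(0, mean_od +
      stats::rnorm(nrow(plate), 0, np$replicate_sd) +
      stats::rnorm(nrow(plate), 0, np$od_sd))
    plate
  })
  plates <- dplyr::select(
    plates, "plate_id", "well", "role", "strain_id", "compound_id",
    "concentration", "replicate_id", "library_id", "od600")

  compounds <- scenario_compounds(scenario)
  desc <- simulate_descriptors(nrow(compounds), fraction_druglike = 0.7,
    seed = derive_seed(np$seed, 777L), fraction_pains = 0.09)
  compounds <- dplyr::bind_cols(
    compounds, dplyr::select(desc, "mw", "logp", "hbd", "hba", "pains_match"))

  mods <- scenario$planted_modulators
  truth <- dplyr::bind_rows(
    if (nrow(mods) > 0) {
      mods |>
        dplyr::group_by(.data$compound_id) |>
        dplyr::summarise(active_strains = paste(sort(.data$strain_id), collapse = ";"),
          .groups = "drop") |>
        dplyr::mutate(type = "modulator")
    },
    if (nrow(scenario$planted_toxics) > 0) {
      tibble::tibble(
        compound_id = scenario$planted_toxics$compound_id,
        active_strains = paste(sort(scenario$strains), collapse = ";"),
        type = "toxic")
    },
    tibble::tibble(
      compound_id = setdiff(compounds$compound_id,
        c(planted_ids(mods), planted_ids(scenario$planted_toxics))),
      active_strains = "", type = "inert")
  )

  kin_ids <- kinetic_compounds %||%
    unique(c(planted_ids(mods), planted_ids(scenario$planted_toxics)))
  kinetics <- simulate_kinetic_traces(scenario, kin_ids)

  structure(
    list(endpoint = plates, kinetics = kinetics, compounds = compounds, truth = truth),
    class = c("screen_campaign", "list")
  )
}

#' Simulate kinetic dual-reporter traces for a compound set
#'
#' One kinetic plate per (strain, reporter, duplicate): the requested
#' compounds at the scenario screening concentration plus matched DMSO
#' wells, measured every `cadence_min` minutes for `duration_h` hours.
#' OD noise is additive Gaussian per read plus a per-well offset;
#' fluorescence noise is multiplicative lognormal with CV
#' `noise$fluor_cv`.
#'
#' @inheritParams simulate_screen
#' @param compound_ids Compounds to trace (must exist in the scenario's
#'   libraries).
#' @return A long tibble, one row per well per cycle, in the
#'   [read_kinetic_traces()] schema.
#' @export
simulate_kinetic_traces <- function(scenario, compound_ids) {
  compounds <- scenario_compounds(scenario)
  unknown <- setdiff(compound_ids, compounds$compound_id)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown compound(s): %s", paste(unknown, collapse = ", ")),
      class = "splicescreenr_scenario_error")
  }
  compound_ids <- unique(compound_ids)
  gp <- scenario$growth
  rp <- scenario$reporter
  np <- scenario$noise
  times <- seq(0, scenario$duration_h * 60, by = scenario$cadence_min)
  n_cyc <- length(times)
  sdlog <- sqrt(log(1 + np$fluor_cv^2))
  conc_of <- compounds$concentration[match(compound_ids, compounds$compound_id)]

  grid <- tidyr::expand_grid(
    strain_id = scenario$strains, reporter = c("SPLIF", "SPLOOF"),
    replicate_id = seq_len(scenario$n_kinetic_replicates))
  purrr::pmap_dfr(grid, function(strain_id, reporter, replicate_id) {
    plate_id <- sprintf("KIN_%s_%s_R%d", strain_id, reporter, replicate_id)
    idx <- 100000L + match(strain_id, scenario$strains) * 1000L +
      match(reporter, c("SPLIF", "SPLOOF")) * 100L + replicate_id
    n_wells <- length(compound_ids) + scenario$n_dmso_kinetic
    wells <- all_wells_384()[seq_len(n_wells)]
    well_tbl <- tibble::tibble(
      well = wells,
      role = c(rep("compound", length(compound_ids)),
        rep("dmso_control", scenario$n_dmso_kinetic)),
      compound_id = c(compound_ids, rep(NA_character_, scenario$n_dmso_kinetic)),
      concentration = c(conc_of, rep(NA_real_, scenario$n_dmso_kinetic))
    )
    conc <- ifelse(is.na(well_tbl$concentration), 0, well_tbl$concentration)
    inh <- planted_inhibition(scenario, well_tbl$compound_id, strain_id, conc)
    inh[is.na(well_tbl$compound_id)] <- 0
    splice_eff <- planted_splice_fraction(scenario, well_tbl$compound_id, strain_id, conc)
    splice_eff[is.na(well_tbl$compound_id)] <- 0
    s <- rp$splicing_efficiency_0 * (1 - splice_eff)
    frac <- if (reporter == "SPLIF") s else (1 - s + rp$leak_sploof)
    yield <- if (reporter == "SPLIF") rp$yield_splif else rp$yield_sploof
    t_h <- times / 60
    r_eff <- gp$r * (1 - inh)
    od_mean <- t(vapply(r_eff, function(re) logistic_od(gp, re, t_h), numeric(n_cyc)))
    b_mean <- t(vapply(r_eff, function(re) {
      biomass_integral(gp, re, pmax(0, t_h - rp$maturation_delay / 60))
    }, numeric(n_cyc)))
    f_mean <- yield * frac * b_mean + rp$autofluor * od_mean

    local_seed(derive_seed(np$seed, idx))
    well_off <- stats::rnorm(n_wells, 0, np$replicate_sd)
    od_obs <- pmax(0, od_mean + well_off +
      matrix(stats::rnorm(n_wells * n_cyc, 0, np$od_sd), n_wells, n_cyc))
    f_obs <- f_mean * matrix(stats::rlnorm(n_wells * n_cyc, -sdlog^2 / 2, sdlog),
      n_wells, n_cyc)

    tibble::tibble(
      plate_id = plate_id,
      well = rep(wells, each = n_cyc),
      role = rep(well_tbl$role, each = n_cyc),
      strain_id = strain_id,
      reporter = reporter,
      compound_id = rep(well_tbl$compound_id, each = n_cyc),
      concentration = rep(well_tbl$concentration, each = n_cyc),
      replicate_id = replicate_id,
      cycle = rep(seq_len(n_cyc), times = n_wells),
      time_min = rep(times, times = n_wells),
      od600 = as.vector(t(od_obs)),
      fluorescence = as.vector(t(f_obs)),
      gapped = FALSE
    )
  })
}

#' Simulate compound descriptor records
#'
#' Draws molecular descriptors so that each record independently passes
#' the strict rule-of-five filter (MW < 500, logP < 5, HBD < 5,
#' HBA < 10) with probability `fraction_druglike`; non-passing records
#' violate at least one cutoff. A fraction `fraction_pains` carry a
#' precomputed PAINS interference flag.
#'
#' @param n Number of compound records.
#' @param fraction_druglike Expected fraction passing the rule of five.
#' @param seed Integer seed.
#' @param fraction_pains Expected fraction with `pains_match = TRUE`.
#' @return A tibble of compound records with descriptor columns.
#' @export
simulate_descriptors <- function(n, fraction_druglike, seed = 1L,
                                 fraction_pains = 0) {
  stopifnot(fraction_druglike >= 0, fraction_druglike <= 1,
    fraction_pains >= 0, fraction_pains <= 1)
  local_seed(as.integer(seed))
  druglike <- stats::runif(n) < fraction_druglike
  mw <- stats::runif(n, 150, 480)
  logp <- stats::runif(n, -1, 4.5)
  hbd <- sample(0:4, n, replace = TRUE)
  hba <- sample(0:9, n, replace = TRUE)
  # non-druglike records get one randomly chosen violated descriptor
  viol <- sample(1:4, n, replace = TRUE)
  fail <- !druglike
  mw[fail & viol == 1] <- stats::runif(sum(fail & viol == 1), 510, 900)
  logp[fail & viol == 2] <- stats::runif(sum(fail & viol == 2), 5.5, 9)
  hbd[fail & viol == 3] <- sample(5:10, sum(fail & viol == 3), replace = TRUE)
  hba[fail & viol == 4] <- sample(10:15, sum(fail & viol == 4), replace = TRUE)
  tibble::tibble(
    compound_id = sprintf("SIM%05d", seq_len(n)),
    library_id = "SIM",
    mw = mw, logp = logp, hbd = hbd, hba = hba,
    pains_match = stats::runif(n) < fraction_pains
  )
}

# Seed scoped to the calling function; restores the caller's RNG state.
local_seed <- function(seed, env = parent.frame()) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  withr::defer(
    if (has_old) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv()),
    envir = env
  )
  invisible(seed)
}
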