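#' Growth, dose-response, reporter and noise parameters
#'
#' Parameter constructors for the synthetic screening campaign
#' simulator. Defaults are calibrated to the assay conditions the
#' pipeline was designed for: wells inoculated at OD600 0.0075 growing
#' to saturation within the 24 h read window, and control separation
#' giving plate Z' factors in the 0.70--0.95 band.
#'
#' @param od0 Starting absorbance (OD600) at inoculation.
#' @param k_cap Carrying capacity (absorbance at saturation).
#' @param r Maximum specific growth rate, per hour.
#' @param lag Lag phase duration, hours.
#' @return A named list of validated parameters with a params subclass.
#' @export
growth_params <- function(od0 = 0.0075, k_cap = 1.0, r = 0.35, lag = 2) {
  stopifnot(od0 > 0, od0 < k_cap, r > 0, lag >= 0)
  structure(list(od0 = od0, k_cap = k_cap, r = r, lag = lag),
    class = c("growth_params", "list"))
}

#' @rdname growth_params
#' @param ec50 Half-maximal inhibitory concentration (micromolar, or the
#'   dispensed mass-per-volume unit for antibiotics such as phleomycin).
#' @param hill Hill coefficient (> 0).
#' @param max_inhibition Maximal fractional inhibition of the growth
#'   rate in `[0, 1]`; 1 freezes growth at the inoculum.
#' @export
dose_response_params <- function(ec50, hill = 2, max_inhibition = 1) {
  stopifnot(ec50 > 0, hill > 0, max_inhibition >= 0, max_inhibition <= 1)
  structure(list(ec50 = ec50, hill = hill, max_inhibition = max_inhibition),
    class = c("dose_response_params", "list"))
}

#' @rdname growth_params
#' @param splicing_efficiency_0 Drug-free splicing efficiency in `[0, 1]`.
#' @param splice_ec50,splice_hill Hill parameters of the drug effect on
#'   splicing efficiency.
#' @param yield_splif,yield_sploof Fluorescence units produced per
#'   absorbance unit of biomass per hour of expression, for the
#'   splicing-in-frame (SPLIF) and splicing-out-of-frame (SPLOOF)
#'   reporters.
#' @param leak_sploof Fractional leaky expression of the SPLOOF reporter
#'   under full splicing.
#' @param maturation_delay Fluorophore maturation delay, minutes.
#' @param autofluor Background autofluorescence per absorbance unit of
#'   biomass (units of fluorescence); small and nonzero by default so
#'   per-cycle DMSO normalisation is always defined.
#' @export
reporter_params <- function(splicing_efficiency_0 = 0.95,
                            splice_ec50 = 1, splice_hill = 2,
                            yield_splif = 1000, yield_sploof = 1000,
                            leak_sploof = 0.02, maturation_delay = 30,
                            autofluor = 5) {
  stopifnot(
    splicing_efficiency_0 >= 0, splicing_efficiency_0 <= 1,
    splice_ec50 > 0, splice_hill > 0,
    yield_splif >= 0, yield_sploof >= 0,
    leak_sploof >= 0, leak_sploof <= 1,
    maturation_delay >= 0, autofluor >= 0
  )
  structure(
    list(
      splicing_efficiency_0 = splicing_efficiency_0,
      splice_ec50 = splice_ec50, splice_hill = splice_hill,
      yield_splif = yield_splif, yield_sploof = yield_sploof,
      leak_sploof = leak_sploof, maturation_delay = maturation_delay,
      autofluor = autofluor
    ),
    class = c("reporter_params", "list")
  )
}

#' @rdname growth_params
#' @param od_sd Additive Gaussian read noise on OD600, absorbance units.
#' @param fluor_cv Multiplicative lognormal coefficient of variation on
#'   fluorescence reads.
#' @param replicate_sd Between-replicate per-well offset SD, absorbance.
#' @param seed Integer master seed; per-plate seeds are derived from it
#'   so plate subsets are reproducible.
#' @export
noise_params <- function(od_sd = 0.012, fluor_cv = 0.05, replicate_sd = 0.015,
                         seed = 1L) {
  stopifnot(od_sd >= 0, fluor_cv >= 0, replicate_sd >= 0)
  structure(
    list(od_sd = od_sd, fluor_cv = fluor_cv, replicate_sd = replicate_sd,
      seed = as.integer(seed)),
    class = c("noise_params", "list")
  )
}

default_strains <- function() c("WT-Hsh155", "Hs-Hsh155", "WT-Brr2", "Hs-Brr2")

#' Define a synthetic screening campaign
#'
#' A `simulation_scenario` fully parameterises a synthetic screen:
#' libraries of (mostly inert) compounds, the four screening strains,
#' planted true splicing modulators with strain-selective dose-response
#' and splicing effects, planted growth-only toxics, growth/reporter/
#' noise parameters, and the assay schedule (24 h at a 15-min cadence).
#'
#' Planted effects are given as a tibble `planted_modulators` with one
#' row per (compound, sensitive strain): columns `compound_id`,
#' `strain_id`, `ec50`, `hill`, `max_inhibition`, `splice_ec50`,
#' `splice_hill`, `splice_max`. Strains without a row are insensitive to
#' that compound. `planted_toxics` (`compound_id`, `ec50`, `hill`,
#' `max_inhibition`) inhibit growth identically in every strain and do
#' not touch splicing.
#'
#' @param libraries Tibble with `library_id`, `n_compounds`,
#'   `n_replicates`, `policy` (`"full_replicate"` or `"cherry_pick"`),
#'   `concentration` (screening concentration, micromolar).
#' @param strains Character vector of 4 strain identifiers.
#' @param planted_modulators,planted_toxics See Details; planted sets
#'   must be disjoint and contained in a library.
#' @param growth,reporter,noise Parameter sets from [growth_params()],
#'   [reporter_params()], [noise_params()].
#' @param duration_h Assay duration, hours.
#' @param cadence_min Kinetic measurement cadence, minutes.
#' @param n_dmso,n_positive Control wells per end-point plate.
#' @param n_dmso_kinetic DMSO wells per kinetic strain/reporter plate.
#' @param n_kinetic_replicates Duplicate kinetic screens per compound.
#' @return A `simulation_scenario` list.
#' @seealso [default_scenario()], [simulate_screen()]
#' @export
simulation_scenario <- function(libraries, strains = default_strains(),
                                planted_modulators, planted_toxics,
                                growth = growth_params(),
                                reporter = reporter_params(),
                                noise = noise_params(),
                                duration_h = 24, cadence_min = 15,
                                n_dmso = 16L, n_positive = 16L,
                                n_dmso_kinetic = 4L,
                                n_kinetic_replicates = 2L) {
  libraries <- tibble::as_tibble(libraries)
  require_columns(libraries, c("library_id", "n_compounds", "n_replicates", "policy",
    "concentration"), "libraries")
  stopifnot(length(strains) == 4, !anyDuplicated(strains))
  planted_modulators <- tibble::as_tibble(planted_modulators)
  planted_toxics <- tibble::as_tibble(planted_toxics)
  if (nrow(planted_modulators) > 0) {
    require_columns(planted_modulators,
      c("compound_id", "strain_id", "ec50", "hill", "max_inhibition",
        "splice_ec50", "splice_hill", "splice_max"), "planted_modulators")
    stopifnot(all(planted_modulators$strain_id %in% strains))
  }
  if (nrow(planted_toxics) > 0) {
    require_columns(planted_toxics, c("compound_id", "ec50", "hill", "max_inhibition"),
      "planted_toxics")
  }
  if (length(intersect(planted_ids(planted_modulators), planted_ids(planted_toxics))) > 0) {
    rlang::abort("planted modulator and toxic sets must be disjoint",
      class = "splicescreenr_scenario_error")
  }
  n_planted <- length(unique(planted_ids(planted_modulators))) + nrow(planted_toxics)
  if (n_planted > sum(libraries$n_compounds)) {
    rlang::abort("more planted compounds than library slots",
      class = "splicescreenr_scenario_error")
  }
  structure(
    list(
      libraries = libraries, strains = strains,
      planted_modulators = planted_modulators, planted_toxics = planted_toxics,
      growth = growth, reporter = reporter, noise = noise,
      duration_h = duration_h, cadence_min = cadence_min,
      n_dmso = as.integer(n_dmso), n_positive = as.integer(n_positive),
      n_dmso_kinetic = as.integer(n_dmso_kinetic),
      n_kinetic_replicates = as.integer(n_kinetic_replicates)
    ),
    class = c("simulation_scenario", "list")
  )
}

#' Default synthetic screening campaign
#'
#' One library of 320 compounds screened at 10 micromolar in all four
#' strains with three full replicates, six planted strain-selective
#' splicing modulators, six planted growth-only toxics, and default
#' growth/reporter/noise calibration.
#'
#' @param seed Integer master seed.
#' @param n_compounds Library size.
#' @return A [simulation_scenario()].
#' @export
default_scenario <- function(seed = 1L, n_compounds = 320L) {
  strains <- default_strains()
  libraries <- tibble::tibble(
    library_id = "LIB1", n_compounds = as.integer(n_compounds),
    n_replicates = 3L, policy = "full_replicate", concentration = 10
  )
  # strain-selective modulators: potent (ec50 well under the 10 uM
  # screening concentration) in their sensitive strains only
  mod_strains <- list(
    MOD1 = "Hs-Hsh155",
    MOD2 = "Hs-Brr2",
    MOD3 = c("Hs-Hsh155", "Hs-Brr2"),
    MOD4 = "WT-Hsh155",
    MOD5 = strains,
    MOD6 = "Hs-Hsh155"
  )
  planted_modulators <- purrr::imap_dfr(mod_strains, function(st, id) {
    tibble::tibble(
      compound_id = id, strain_id = st,
      ec50 = 1.5, hill = 2, max_inhibition = 0.9,
      splice_ec50 = 1.5, splice_hill = 2, splice_max = 0.95
    )
  })
  planted_toxics <- tibble::tibble(
    compound_id = paste0("TOX", 1:6),
    ec50 = 2, hill = 2, max_inhibition = c(1, 1, 0.9, 0.8, 1, 0.7)
  )
  simulation_scenario(
    libraries = libraries, strains = strains,
    planted_modulators = planted_modulators, planted_toxics = planted_toxics,
    noise = noise_params(seed = seed)
  )
}

#' Serialise a scenario to JSON
#'
#' @param scenario A [simulation_scenario()].
#' @param path File path to write to / read from.
#' @return `read_scenario()` returns the reconstructed scenario.
#' @export
write_scenario <- function(scenario, path) {
  jsonlite::write_json(unclass_deep(scenario), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  simulation_scenario(
    libraries = x$libraries, strains = x$strains,
    planted_modulators = x$planted_modulators, planted_toxics = x$planted_toxics,
    growth = do.call(growth_params, x$growth),
    reporter = do.call(reporter_params, x$reporter),
    noise = do.call(noise_params, x$noise),
    duration_h = x$duration_h, cadence_min = x$cadence_min,
    n_dmso = x$n_dmso, n_positive = x$n_positive,
    n_dmso_kinetic = x$n_dmso_kinetic,
    n_kinetic_replicates = x$n_kinetic_replicates
  )
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

# Column-safe compound ids of a possibly empty planted-effect table.
planted_ids <- function(df) {
  if (nrow(df) == 0 || !"compound_id" %in% names(df)) character(0) else df$compound_id
}

# Per-plate seed derived from the scenario master seed; kept under 2^31.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(index)) %% 2147483647)
}
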