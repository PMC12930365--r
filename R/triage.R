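#' Lipinski rule-of-five triage
#'
#' Applies the four oral-druglikeness cutoffs with strict inequalities
#' as conventionally printed: molecular weight < 500 g/mol, logP < 5,
#' hydrogen-bond donors < 5, hydrogen-bond acceptors < 10. In the
#' default strict mode a compound is druglike only with zero
#' violations; the classical one-violation tolerance is available via
#' `max_violations = 1`. Compounds missing any descriptor are a
#' separate not-evaluable class (as happens for libraries distributed
#' without structural information) and are excluded from the druglike
#' denominator.
#'
#' @param compounds Tibble of compound records with columns `mw`,
#'   `logp`, `hbd`, `hba` (and usually `compound_id`).
#' @param max_violations Violations tolerated while still counting as
#'   druglike (default 0, strict).
#' @return The input with `mw_ok`, `logp_ok`, `hbd_ok`, `hba_ok`,
#'   `n_violations`, `evaluable`, `druglike` columns added; `druglike`
#'   is `NA` for non-evaluable records.
#' @examples
#' rule_of_five(tibble::tibble(compound_id = "x", mw = 250, logp = 2, hbd = 1, hba = 4))
#' @export
rule_of_five <- function(compounds, max_violations = 0L) {
  compounds <- tibble::as_tibble(compounds)
  require_columns(compounds, c("mw", "logp", "hbd", "hba"), "compound table")
  compounds |>
    dplyr::mutate(
      mw_ok = .data$mw < 500,
      logp_ok = .data$logp < 5,
      hbd_ok = .data$hbd < 5,
      hba_ok = .data$hba < 10,
      evaluable = !is.na(.data$mw) & !is.na(.data$logp) &
        !is.na(.data$hbd) & !is.na(.data$hba),
      n_violations = dplyr::if_else(.data$evaluable,
        (!.data$mw_ok) + (!.data$logp_ok) + (!.data$hbd_ok) + (!.data$hba_ok),
        NA_integer_),
      druglike = dplyr::if_else(.data$evaluable,
        .data$n_violations <= max_violations, NA))
}

#' PAINS interference triage
#'
#' Flags pan-assay interference compounds. A precomputed `pains_match`
#' flag in the record takes precedence; otherwise a pluggable
#' substructure matcher (a function taking a vector of structure
#' line-notation strings and returning logical matches) is applied to
#' records with structures. Records with neither flag nor usable
#' structure are `not_evaluable`; the core package deliberately carries
#' no chemistry dependency, so external engines plug in here.
#'
#' @param compounds Tibble of compound records; optional columns
#'   `pains_match` (logical) and `structure` (character).
#' @param matcher Optional `function(structure) -> logical`.
#' @return The input with a `pains` column: `"pass"`, `"fail"` or
#'   `"not_evaluable"`.
#' @export
pains_screen <- function(compounds, matcher = NULL) {
  compounds <- tibble::as_tibble(compounds)
  n <- nrow(compounds)
  flag <- if ("pains_match" %in% names(compounds)) compounds$pains_match else rep(NA, n)
  structure_str <- if ("structure" %in% names(compounds)) compounds$structure else
    rep(NA_character_, n)
  res <- dplyr::if_else(is.na(flag), NA_character_,
    dplyr::if_else(flag, "fail", "pass"))
  need <- is.na(res) & !is.na(structure_str)
  if (any(need)) {
    if (is.null(matcher)) {
      rlang::warn(paste0(
        "structures present but no PAINS matcher configured; ",
        sum(need), " compound(s) left not_evaluable"))
    } else {
      m <- matcher(structure_str[need])
      res[need] <- dplyr::if_else(m, "fail", "pass")
    }
  }
  compounds$pains <- dplyr::coalesce(res, "not_evaluable")
  compounds
}

#' Percent spliced from RT-PCR band intensities
#'
#' `percent_spliced = mRNA / (pre-mRNA + mRNA)` from gel band
#' intensities, the fraction of transcripts whose intron was removed.
#' Scale-invariant in the band intensities; its complement is the
#' unspliced fraction. Both bands zero is an undefined measurement and
#' raises an error.
#'
#' @param band_mRNA,band_pre Nonnegative band intensities (vectorised).
#' @return Fraction spliced in `[0, 1]`.
#' @examples
#' percent_spliced(band_mRNA = 3, band_pre = 1)
#' @export
percent_spliced <- function(band_mRNA, band_pre) {
  if (any(band_mRNA < 0, na.rm = TRUE) || any(band_pre < 0, na.rm = TRUE)) {
    rlang::abort("band intensities must be >= 0", class = "splicescreenr_domain_error")
  }
  both_zero <- band_mRNA == 0 & band_pre == 0
  if (any(both_zero, na.rm = TRUE)) {
    rlang::abort("undefined measurement: both band intensities are zero",
      class = "splicescreenr_measurement_error")
  }
  band_mRNA / (band_pre + band_mRNA)
}

#' Compare treated splicing measurements to a control group
#'
#' Normalises percent-spliced values to the control-group mean and
#' tests the treated group against the control with an unpaired
#' two-tailed Welch (unequal-variance) t-test, using the
#' Welch-Satterthwaite degrees of freedom. Significance tiers follow
#' the usual star convention: `*` p < 0.05, `**` p < 0.005,
#' `***` p < 0.001.
#'
#' @param treated,control Numeric vectors of percent-spliced values
#'   (>= 2 replicates each; typically 3--4 biological replicates).
#' @return An object of class `splicing_comparison`; `glance()` returns
#'   a one-row tibble with the normalised means, `t`, `df`, `p_value`
#'   and `stars`; `tidy()` returns the normalised per-replicate values.
#' @examples
#' cmp <- compare_to_control(c(0.5, 0.45, 0.55), c(0.9, 0.8, 0.85))
#' glance(cmp)
#' @export
compare_to_control <- function(treated, control) {
  treated <- treated[!is.na(treated)]
  control <- control[!is.na(control)]
  if (length(treated) < 2 || length(control) < 2) {
    rlang::abort("compare_to_control needs >= 2 replicates per group",
      class = "splicescreenr_insufficient_replicates")
  }
  ref <- mean(control)
  norm_treated <- treated / ref
  norm_control <- control / ref
  se2 <- stats::var(treated) / length(treated) + stats::var(control) / length(control)
  if (se2 == 0) {
    if (mean(treated) != mean(control)) {
      rlang::abort("groups are constant with different means; t is undefined",
        class = "splicescreenr_degenerate_test")
    }
    t_stat <- 0; df <- length(treated) + length(control) - 2; p <- 1
  } else {
    tt <- stats::t.test(treated, control, var.equal = FALSE)
    t_stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  stars <- if (p < 0.001) "***" else if (p < 0.005) "**" else if (p < 0.05) "*" else ""
  structure(
    list(
      t = t_stat, df = df, p_value = p, stars = stars,
      mean_treated = mean(treated), mean_control = mean(control),
      norm_mean_treated = mean(norm_treated),
      normalized = tibble::tibble(
        group = c(rep("treated", length(treated)), rep("control", length(control))),
        value = c(treated, control),
        normalized = c(norm_treated, norm_control))),
    class = "splicing_comparison")
}

#' @export
print.splicing_comparison <- function(x, ...) {
  cat(sprintf(
    "Welch two-sample comparison: t = %.4f, df = %.2f, p = %.4g %s\n",
    x$t, x$df, x$p_value, x$stars))
  cat(sprintf("  treated mean %.4f (%.3f of control), control mean %.4f\n",
    x$mean_treated, x$norm_mean_treated, x$mean_control))
  invisible(x)
}

#' @export
tidy.splicing_comparison <- function(x, ...) x$normalized

#' @export
glance.splicing_comparison <- function(x, ...) {
  tibble::tibble(
    mean_treated = x$mean_treated, mean_control = x$mean_control,
    norm_mean_treated = x$norm_mean_treated,
    t = x$t, df = x$df, p_value = x$p_value, stars = x$stars)
}
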