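#' Z-prime screening-window factor
#'
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`, computed on
#' positive- versus negative-control wells of a plate. Values between
#' 0.5 and 1.0 indicate a robust, high-quality assay; the conventional
#' pass threshold is 0.5. Standard deviations are sample (n - 1) SDs,
#' the HTS convention. The statistic is invariant to swapping the two
#' control-group labels and to affine rescaling of the absorbances.
#'
#' @param neg Absorbance values of negative-control (DMSO) wells.
#' @param pos Absorbance values of positive-control wells.
#' @param plate_id Optional plate identifier carried into the result.
#' @param threshold Pass threshold on Z' (default 0.5).
#' @return An object of class `z_prime`; `glance()` gives a one-row
#'   tibble with `mu_neg`, `sd_neg`, `mu_pos`, `sd_pos`, `z_prime`,
#'   `pass`.
#' @examples
#' z_prime(neg = c(0.95, 1.0, 1.05), pos = c(0.05, 0.10, 0.15))
#' @export
z_prime <- function(neg, pos, plate_id = NA_character_, threshold = 0.5) {
  neg <- neg[!is.na(neg)]
  pos <- pos[!is.na(pos)]
  if (length(neg) < 2 || length(pos) < 2) {
    rlang::abort("z_prime needs >= 2 values per control group",
      class = "splicescreenr_qc_error")
  }
  mu_n <- mean(neg); mu_p <- mean(pos)
  sd_n <- stats::sd(neg); sd_p <- stats::sd(pos)
  if (mu_p == mu_n) {
    rlang::abort("Z' undefined: control group means are equal",
      class = "splicescreenr_qc_error")
  }
  z <- 1 - 3 * (sd_p + sd_n) / abs(mu_p - mu_n)
  structure(
    list(plate_id = plate_id, mu_neg = mu_n, sd_neg = sd_n,
      mu_pos = mu_p, sd_pos = sd_p, z_prime = z,
      pass = z >= threshold, threshold = threshold,
      sign_warning = mu_p > mu_n),
    class = "z_prime")
}

#' @export
print.z_prime <- function(x, ...) {
  cat(sprintf("Z' = %.3f (%s at threshold %.2f)\n", x$z_prime,
    if (x$pass) "pass" else "FAIL", x$threshold))
  cat(sprintf("  neg: mean %.4f, sd %.4f   pos: mean %.4f, sd %.4f\n",
    x$mu_neg, x$sd_neg, x$mu_pos, x$sd_pos))
  if (x$sign_warning) cat("  note: positive-control mean exceeds negative-control mean\n")
  invisible(x)
}

#' @export
glance.z_prime <- function(x, ...) {
  tibble::tibble(
    plate_id = x$plate_id, mu_neg = x$mu_neg, sd_neg = x$sd_neg,
    mu_pos = x$mu_pos, sd_pos = x$sd_pos, z_prime = x$z_prime, pass = x$pass)
}

#' Per-plate quality-control table
#'
#' Computes the Z' factor of every plate in a long end-point table from
#' its DMSO (negative) and positive-control wells.
#'
#' @param plates Long end-point tibble ([read_endpoint_plates()] /
#'   [simulate_screen()] schema).
#' @param threshold Z' pass threshold.
#' @return A tibble with one row per plate: control means/SDs,
#'   `z_prime`, `pass`, and `reason` (`NA` when computable).
#' @export
plate_qc <- function(plates, threshold = 0.5) {
  plates |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::group_modify(function(df, key) {
      neg <- df$od600[df$role == "dmso_control"]
      pos <- df$od600[df$role == "positive_control"]
      res <- tryCatch(
        glance(z_prime(neg, pos, threshold = threshold)) |>
          dplyr::select(-"plate_id") |>
          dplyr::mutate(reason = NA_character_),
        splicescreenr_qc_error = function(e) {
          tibble::tibble(mu_neg = NA_real_, sd_neg = NA_real_, mu_pos = NA_real_,
            sd_pos = NA_real_, z_prime = NA_real_, pass = FALSE,
            reason = conditionMessage(e))
        })
      res
    }) |>
    dplyr::ungroup()
}

#' Gate plates on Z' quality
#'
#' Partitions plates into QC-passing and QC-failing sets; failing plates
#' (Z' below threshold, or Z' not computable) are excluded from hit
#' calling and listed with reasons. Plates whose positive-control mean
#' exceeds the negative-control mean still yield a valid Z' (the formula
#' uses the absolute mean difference) but are flagged.
#'
#' @inheritParams plate_qc
#' @param z_threshold Z' threshold (default 0.5).
#' @return A list with tibbles `passing`, `failing` (plate rows), and
#'   `qc` (the [plate_qc()] table with a `sign_warning` column).
#' @export
qc_gate <- function(plates, z_threshold = 0.5) {
  qc <- plate_qc(plates, threshold = z_threshold) |>
    dplyr::mutate(
      sign_warning = !is.na(.data$z_prime) & .data$mu_pos > .data$mu_neg,
      reason = dplyr::if_else(
        !.data$pass & is.na(.data$reason),
        sprintf("Z' %.3f below threshold %.2f", .data$z_prime, z_threshold),
        .data$reason))
  pass_ids <- qc$plate_id[qc$pass]
  list(
    passing = dplyr::filter(plates, .data$plate_id %in% pass_ids),
    failing = dplyr::filter(plates, !.data$plate_id %in% pass_ids),
    qc = qc
  )
}

#' Bland-Altman agreement between replicate plates
#'
#' For each well measured in both replicates, the difference
#' `rep1 - rep2` is paired with the mean `(rep1 + rep2) / 2`. The bias
#' is the mean difference and the 95% limits of agreement are
#' `bias +/- 1.96 * SD(differences)`, summarising the maximum expected
#' variability between biological replicates.
#'
#' @param rep1,rep2 Either numeric vectors of per-well values (same well
#'   order), or long end-point tibbles for one plate each, matched on
#'   `well`.
#' @return An object of class `bland_altman`; `tidy()` returns the
#'   per-well (mean, difference) pairs, `glance()` the bias and limits.
#' @examples
#' ba <- bland_altman(c(1.0, 0.9, 1.1), c(1.1, 0.9, 1.0))
#' glance(ba)
#' @export
bland_altman <- function(rep1, rep2) {
  if (is.data.frame(rep1)) {
    joined <- dplyr::inner_join(
      dplyr::select(rep1, "well", v1 = "od600"),
      dplyr::select(rep2, "well", v2 = "od600"), by = "well")
    well <- joined$well; rep1 <- joined$v1; rep2 <- joined$v2
  } else {
    if (length(rep1) != length(rep2)) {
      rlang::abort("replicate vectors must cover the same wells",
        class = "splicescreenr_qc_error")
    }
    well <- seq_along(rep1)
  }
  ok <- !is.na(rep1) & !is.na(rep2)
  well <- well[ok]; rep1 <- rep1[ok]; rep2 <- rep2[ok]
  if (length(rep1) < 3) {
    rlang::abort("bland_altman needs >= 3 common wells",
      class = "splicescreenr_insufficient_data")
  }
  diffs <- rep1 - rep2
  means <- (rep1 + rep2) / 2
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  structure(
    list(
      pairs = tibble::tibble(well = well, mean = means, difference = diffs),
      bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
      sd_diff = s, n = length(diffs)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement over %d wells\n", x$n))
  cat(sprintf("  bias %.4f, 95%% limits of agreement [%.4f, %.4f]\n",
    x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) x$pairs

#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high)
}
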