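# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A minimal end-point plate tibble with explicit control values.
make_plate <- function(plate_id = "P1", strain_id = "Hs-Hsh155", replicate_id = 1L,
                       neg = c(0.95, 1.00, 1.05, 1.00), pos = c(0.05, 0.10, 0.15, 0.10),
                       compound_od = numeric(0), compound_ids = NULL) {
  n_c <- length(compound_od)
  if (is.null(compound_ids) && n_c > 0) compound_ids <- sprintf("C%03d", seq_len(n_c))
  tibble::tibble(
    plate_id = plate_id,
    well = format_well(rep(1:16, length.out = n_c + length(neg) + length(pos)),
      rep(1:24, each = 16, length.out = n_c + length(neg) + length(pos))),
    role = c(rep("compound", n_c), rep("dmso_control", length(neg)),
      rep("positive_control", length(pos))),
    strain_id = strain_id,
    compound_id = c(compound_ids, rep(NA_character_, length(neg) + length(pos))),
    concentration = c(rep(10, n_c), rep(NA_real_, length(neg) + length(pos))),
    replicate_id = replicate_id,
    library_id = "LIB1",
    od600 = c(compound_od, neg, pos)
  )
}

# A small but complete campaign scenario (fast enough for unit tests).
mini_scenario <- function(seed = 11L, n_compounds = 40L) {
  default_scenario(seed = seed, n_compounds = n_compounds)
}

# Independent textbook Welch statistic, written from the formula, used
# as the oracle for compare_to_control().
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Brute-force window enumeration: does any window of k consecutive
# cycles have all cycles qualifying? Checks every start explicitly.
brute_force_has_run <- function(q, k) {
  n <- length(q)
  if (n < k || k < 1) return(FALSE)
  for (s in seq_len(n - k + 1)) {
    if (all(q[s:(s + k - 1)])) return(TRUE)
  }
  FALSE
}

# Brute-force maximal-run enumeration (start, length) over a logical
# vector, by explicit scanning.
brute_force_runs <- function(q) {
  runs <- list()
  i <- 1L
  n <- length(q)
  while (i <= n) {
    if (isTRUE(q[i])) {
      j <- i
      while (j < n && isTRUE(q[j + 1L])) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(start = i, len = j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  runs
}
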