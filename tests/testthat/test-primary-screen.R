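test_that("growth normalisation is exact against the plate DMSO mean", {
  plate <- make_plate("P1", neg = rep(0.5, 4), pos = rep(0.05, 4),
    compound_od = c(0.5, 0.35, 0.6))
  rec <- normalize_growth(plate)
  expect_equal(rec$inhibition, c(0, 0.30, -0.20), tolerance = 1e-12)
  expect_equal(rec$growth_fraction, c(1, 0.7, 1.2), tolerance = 1e-12)
  # a dead DMSO reference is a plate error
  bad <- make_plate("P2", neg = rep(0, 4), compound_od = 0.2)
  expect_error(normalize_growth(bad), class = "splicescreenr_plate_error")
})

test_that("the all-replicates consistency rule decides hits at the 30% threshold", {
  mk <- function(inhib) {
    tibble::tibble(compound_id = "C1", strain_id = "Hs-Hsh155",
      replicate_id = seq_along(inhib), plate_id = paste0("P", seq_along(inhib)),
      well = "A01", od600 = NA_real_, dmso_mean = NA_real_,
      growth_fraction = 1 - inhib, inhibition = inhib)
  }
  hit <- call_primary_hits(mk(c(0.35, 0.40, 0.32)))
  expect_true(hit$is_hit)
  # one replicate below threshold sinks the compound
  miss <- call_primary_hits(mk(c(0.35, 0.25, 0.40)))
  expect_false(miss$is_hit)
  # threshold comparison is inclusive
  exact <- call_primary_hits(mk(c(0.30, 0.30, 0.30)))
  expect_true(exact$is_hit)
  # mean rule behind the flag
  mean_rule <- call_primary_hits(mk(c(0.35, 0.25, 0.40)), rule = "mean")
  expect_true(mean_rule$is_hit)
  # stimulation can never qualify
  stim <- call_primary_hits(mk(c(-0.2, -0.1, -0.3)))
  expect_false(stim$is_hit)
  # fewer replicates than the policy demands: flagged incomplete
  inc <- call_primary_hits(mk(c(0.4, 0.5)))
  expect_false(inc$is_hit)
  expect_equal(inc$status, "incomplete")
})

test_that("cherry-pick mode gates on the first pass before the consistency rule", {
  pol <- replicate_policy("cherry_pick", n_total = 3, qualifier_threshold = 0.30)
  rec <- tibble::tibble(
    compound_id = c("Q", "Q", "Q", "NQ"),
    strain_id = "S1",
    replicate_id = c(1L, 2L, 3L, 1L),
    plate_id = "P1", well = "A01", od600 = NA_real_, dmso_mean = NA_real_,
    growth_fraction = NA_real_,
    inhibition = c(0.40, 0.35, 0.33, 0.10))
  out <- call_primary_hits(rec, policy = pol)
  expect_true(out$is_hit[out$compound_id == "Q"])
  nq <- out[out$compound_id == "NQ", ]
  expect_false(nq$is_hit)
  expect_equal(nq$status, "not_qualified")
  # a qualifier that was never rescreened is incomplete, not a hit
  part <- call_primary_hits(rec[c(1, 2), ], policy = pol)
  expect_equal(part$status, "incomplete")
  expect_false(part$is_hit)
  expect_error(replicate_policy("cherry_pick", n_total = 1),
    class = "splicescreenr_policy_error")
})

test_that("hit calling matches a brute-force recomputation on a planted screen", {
  sc <- mini_scenario(seed = 23)
  camp <- simulate_screen(sc, kinetic_compounds = character(0))
  rec <- normalize_growth(camp$endpoint)
  out <- call_primary_hits(rec, threshold = 0.30)
  # independent oracle: explicit loop over every compound x strain group
  for (cid in unique(rec$compound_id)) {
    for (sid in unique(rec$strain_id)) {
      inh <- rec$inhibition[rec$compound_id == cid & rec$strain_id == sid]
      want <- length(inh) >= 3 && all(inh >= 0.30)
      got <- out$is_hit[out$compound_id == cid & out$strain_id == sid]
      expect_identical(got, want)
    }
  }
})

test_that("raising the threshold never adds a hit; zero keeps non-stimulated ones", {
  sc <- mini_scenario(seed = 29)
  rec <- normalize_growth(simulate_screen(sc, kinetic_compounds = character(0))$endpoint)
  thresholds <- c(0, 0.15, 0.30, 0.45, 0.60)
  hit_sets <- lapply(thresholds, function(th) {
    out <- call_primary_hits(rec, threshold = th)
    paste(out$compound_id, out$strain_id)[out$is_hit]
  })
  for (i in seq_len(length(thresholds) - 1)) {
    expect_true(all(hit_sets[[i + 1]] %in% hit_sets[[i]]))
  }
  # at threshold 0 every consistently non-stimulated group is a hit
  out0 <- call_primary_hits(rec, threshold = 0)
  grp <- dplyr::summarise(dplyr::group_by(rec, compound_id, strain_id),
    all_pos = all(inhibition >= 0), n = dplyr::n(), .groups = "drop")
  want <- grp$all_pos & grp$n >= 3
  expect_identical(out0$is_hit[order(out0$compound_id, out0$strain_id)],
    want[order(grp$compound_id, grp$strain_id)])
})

test_that("hit decisions are invariant to re-partitioning wells across plates", {
  plate <- make_plate("ONE", neg = rep(0.5, 8), pos = rep(0.05, 8),
    compound_od = c(0.30, 0.40, 0.20, 0.10))
  split <- dplyr::bind_rows(
    make_plate("A", neg = rep(0.5, 4), pos = rep(0.05, 4),
      compound_od = c(0.30, 0.40), compound_ids = c("C001", "C002")),
    make_plate("B", neg = rep(0.5, 4), pos = rep(0.05, 4),
      compound_od = c(0.20, 0.10), compound_ids = c("C003", "C004")))
  pol <- replicate_policy(n_total = 1)
  one <- call_primary_hits(normalize_growth(plate), policy = pol)
  two <- call_primary_hits(normalize_growth(split), policy = pol)
  expect_equal(one[order(one$compound_id), c("compound_id", "is_hit", "min_inhibition")],
    two[order(two$compound_id), c("compound_id", "is_hit", "min_inhibition")])
})

test_that("selectivity partition is an exhaustive disjoint 15-class Venn", {
  strains <- c("WT-Hsh155", "Hs-Hsh155", "WT-Brr2", "Hs-Brr2")
  # random hit table over 100 compounds
  withr::local_seed(37)
  rows <- purrr::map_dfr(sprintf("C%03d", 1:100), function(cid) {
    hit_in <- sample(strains, sample(1:4, 1))
    tibble::tibble(compound_id = cid, strain_id = hit_in, is_hit = TRUE)
  })
  part <- selectivity_partition(rows, strains)
  expect_equal(nrow(part), 15)
  expect_equal(sum(part$n_compounds), 100)
  # a compound hit only in the humanised Hsh155 strain lands in that singleton
  solo <- selectivity_partition(
    tibble::tibble(compound_id = "X", strain_id = "Hs-Hsh155", is_hit = TRUE), strains)
  expect_equal(solo$n_compounds[solo$strains == "Hs-Hsh155"], 1)
  # a compound hit in all four is a general growth inhibitor
  all4 <- selectivity_partition(
    tibble::tibble(compound_id = "Y", strain_id = strains, is_hit = TRUE), strains)
  expect_equal(all4$n_compounds[all4$n_strains == 4], 1)
  expect_error(
    selectivity_partition(
      tibble::tibble(compound_id = "Z", strain_id = "Mystery", is_hit = TRUE), strains),
    class = "splicescreenr_config_error")
})

test_that("false positives among planted inert compounds stay at zero-ish rates", {
  fp <- vapply(1:5, function(s) {
    sc <- mini_scenario(seed = 100 + s, n_compounds = 100L)
    camp <- simulate_screen(sc, kinetic_compounds = character(0))
    out <- call_primary_hits(normalize_growth(camp$endpoint))
    inert <- camp$truth$compound_id[camp$truth$type == "inert"]
    mean(inert %in% out$compound_id[out$is_hit])
  }, numeric(1))
  expect_lte(mean(fp), 0.01)
})
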