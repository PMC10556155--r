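test_that("candidate enumeration respects polarity and the RT window", {
  # positive-mode analyte at RT 10 with ILIS at 7.9 / 8.1 / 12.1:
  # only the 8.1 candidate is inside the +/-2 min window
  analytes <- tibble::tibble(
    analyte_id = "A1", name = "a", pesticide_class = "herbicide",
    polarity = "positive", expected_rt = 10,
    stereoisomer_group = NA_character_,
    si_ilis_id = NA_character_, assigned_ilis_id = NA_character_
  )
  ilis <- tibble::tibble(
    ilis_id = c("IL1", "IL2", "IL3", "IL4"),
    name = letters[1:4],
    polarity = c("positive", "positive", "positive", "negative"),
    expected_rt = c(7.9, 8.1, 12.1, 10.0),
    tier_concentration = 250
  )
  species <- c("A1", ilis$ilis_id)
  transitions <- tibble::tibble(
    species_id = rep(species, each = 2),
    role = rep(c("quantifier", "qualifier"), 5),
    precursor_mz = 300, product_mz = rep(c(150, 100), 5),
    polarity = rep(c("positive", "positive", "positive", "positive",
                     "negative"), each = 2),
    expected_rt = rep(c(10, 7.9, 8.1, 12.1, 10), each = 2)
  )
  cfg <- method_config(analytes, ilis, transitions)
  cand <- enumerate_candidates(cfg, "A1")
  expect_equal(cand$ilis_id, "IL2")
  expect_equal(cand$delta_rt, 1.9)

  # the window boundary is inclusive
  cfg2 <- cfg
  cfg2$ilis$expected_rt[1] <- 8.0
  cand2 <- enumerate_candidates(cfg2, "A1")
  expect_setequal(cand2$ilis_id, c("IL1", "IL2"))

  # negative mode: all same-polarity ILIS, no RT restriction
  cfg3 <- cfg
  cfg3$analytes$polarity <- "negative"
  cfg3$transitions$polarity[1:2] <- "negative"
  cand3 <- enumerate_candidates(cfg3, "A1")
  expect_equal(cand3$ilis_id, "IL4")

  # an empty candidate set is a typed error
  cfg4 <- cfg
  cfg4$ilis <- cfg4$ilis[cfg4$ilis$polarity == "negative", ]
  cfg4$transitions <- cfg4$transitions[
    cfg4$transitions$species_id %in% c("A1", "IL4"), ]
  expect_error(enumerate_candidates(cfg4, "A1"),
               class = "soilmrm_assignment_impossible_error")
})

test_that("a negative-mode method offers every negative ILIS per analyte", {
  cfg <- simulate_method_config(seed = 101)
  neg_nsi <- cfg$analytes$analyte_id[cfg$analytes$polarity == "negative" &
                                       is.na(cfg$analytes$si_ilis_id)]
  expect_length(neg_nsi, 11)
  for (aid in neg_nsi) {
    expect_equal(nrow(enumerate_candidates(cfg, aid)), 8)
  }
})

test_that("analytes with a structure-identical ILIS are never reassigned", {
  cfg <- simulate_method_config(n_analytes = 6, n_ilis = 4, seed = 4,
                                n_negative_ilis = 0, n_negative_nsi = 0)
  expect_error(enumerate_candidates(cfg, "A001"),
               class = "soilmrm_config_error")
  expect_error(
    assign_ilis(cfg, tibble::tibble(analyte_id = "A001", ilis_id = "IL002")),
    class = "soilmrm_config_error"
  )
})

test_that("selection maximises in-band soils, then dispersion, then delta RT", {
  rec <- function(aid, iid, drt, recs) {
    tibble::tibble(analyte_id = aid, ilis_id = iid, delta_rt = drt,
                   soil_id = sprintf("S%d", seq_along(recs)),
                   recovery_pct = recs)
  }
  # dominance on in-band count
  r1 <- dplyr::bind_rows(
    rec("A", "ILa", 1.0, c(95, 100, 105, 110, 98)),
    rec("A", "ILb", 0.2, c(95, 100, 105, 130, 98))
  )
  s1 <- score_and_select(r1)
  expect_equal(s1$assignments$ilis_id, "ILa")
  expect_true(s1$assignments$all_in_band)

  # tie on count: smaller dispersion wins
  r2 <- dplyr::bind_rows(
    rec("A", "ILa", 1.0, c(96, 104, 100, 104, 96)),   # dispersion 16
    rec("A", "ILb", 0.2, c(93, 107, 100, 107, 93))    # dispersion 28
  )
  s2 <- score_and_select(r2)
  expect_equal(s2$assignments$ilis_id, "ILa")
  expect_equal(s2$assignments$dispersion, 16)

  # tie on count and dispersion: smaller |delta RT| wins
  r3 <- dplyr::bind_rows(
    rec("A", "ILa", 1.0, c(96, 104, 100, 104, 96)),
    rec("A", "ILb", -0.2, c(104, 96, 100, 96, 104))
  )
  s3 <- score_and_select(r3)
  expect_equal(s3$assignments$ilis_id, "ILb")

  # full tie: lexicographic ILIS id keeps the order deterministic
  r4 <- dplyr::bind_rows(
    rec("A", "ILb", 0.5, c(100, 100, 100, 100, 100)),
    rec("A", "ILa", -0.5, c(100, 100, 100, 100, 100))
  )
  expect_equal(score_and_select(r4)$assignments$ilis_id, "ILa")

  # the audit trail ranks every candidate
  expect_equal(sort(s1$audit$rank), 1:2)
})

test_that("assignments freeze into the config with a diff report", {
  cfg <- simulate_method_config(n_analytes = 6, n_ilis = 4, seed = 4,
                                n_negative_ilis = 0, n_negative_nsi = 0)
  asg <- tibble::tibble(analyte_id = c("A005", "A006"),
                        ilis_id = c("IL001", "IL002"))
  cfg1 <- assign_ilis(cfg, asg)
  expect_equal(
    cfg1$analytes$assigned_ilis_id[match(c("A005", "A006"),
                                         cfg1$analytes$analyte_id)],
    c("IL001", "IL002")
  )
  expect_equal(nrow(attr(cfg1, "assignment_diff")), 0)

  # re-running with a different selection reports a diff, keeps the old
  asg2 <- tibble::tibble(analyte_id = "A005", ilis_id = "IL003")
  expect_message(cfg2 <- assign_ilis(cfg1, asg2), "previous assignment")
  expect_equal(cfg2$analytes$assigned_ilis_id[
    cfg2$analytes$analyte_id == "A005"], "IL001")
  expect_equal(attr(cfg2, "assignment_diff")$new_ilis_id, "IL003")

  cfg3 <- assign_ilis(cfg1, asg2, overwrite = TRUE)
  expect_equal(cfg3$analytes$assigned_ilis_id[
    cfg3$analytes$analyte_id == "A005"], "IL003")
})

test_that("recovery-based selection is deterministic across repeated runs", {
  cfg <- simulate_method_config(n_analytes = 8, n_ilis = 6, seed = 12,
                                n_negative_ilis = 6, n_negative_nsi = 2,
                                rt_range = c(8, 12))
  sc <- sim_scenario(seed = 33)
  design <- dplyr::bind_rows(
    design_calibration(cfg, n_injections = 1),
    design_recovery(c("S1", "S2", "S3", "S4", "S5"), n_replicates = 2)
  )
  batch <- simulate_batch(sc, design, cfg)
  nsi <- cfg$analytes$analyte_id[is.na(cfg$analytes$si_ilis_id)]
  cand <- dplyr::bind_rows(lapply(nsi, function(a) {
    enumerate_candidates(cfg, a)
  }))
  run <- function() {
    recs <- candidate_recoveries(batch$measurements, cfg, design,
                                 sc$soils, cand)
    score_and_select(recs)$assignments
  }
  expect_identical(run(), run())
})
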