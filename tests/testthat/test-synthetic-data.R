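test_that("a fixed seed reproduces a batch bit for bit", {
  cfg <- simulate_method_config(n_analytes = 8, n_ilis = 6, seed = 4,
                                n_negative_ilis = 0, n_negative_nsi = 0)
  sc <- sim_scenario(seed = 42)
  design <- design_calibration(cfg, n_injections = 1)
  b1 <- simulate_batch(sc, design, cfg)
  b2 <- simulate_batch(sc, design, cfg)
  expect_identical(b1$measurements, b2$measurements)

  b3 <- simulate_batch(sim_scenario(seed = 43), design, cfg)
  expect_false(identical(b1$measurements$peak_area,
                         b3$measurements$peak_area))
})

test_that("noise-free calibration back-computes every nominal level exactly", {
  cfg <- simulate_method_config(n_analytes = 6, n_ilis = 6, seed = 4,
                                n_negative_ilis = 0, n_negative_nsi = 0)
  sc <- noise_free_scenario()
  design <- design_calibration(cfg)
  batch <- simulate_batch(sc, design, cfg)
  curves <- calibrate_batch(batch$measurements, cfg, design)
  expect_true(all(curves$fitted))
  for (cu in curves$curve) {
    dev <- abs(cu$level_backcalc$backcalc - cu$level_backcalc$nominal) /
      cu$level_backcalc$nominal
    expect_lt(max(dev), 1e-9)
  }
})

test_that("injected suppression scales with organic carbon as specified", {
  # two soils at 1% and 5% C_org with slope -8 and no dispersion:
  # expected median matrix effects differ by exactly -32 points
  soils <- soil_table(c("LOW", "HIGH", "S2", "SOLVENT"),
                      c_org_pct = c(1, 5, 2, 0))
  cfg <- simulate_method_config(n_analytes = 6, n_ilis = 6, seed = 4,
                                n_negative_ilis = 0, n_negative_nsi = 0)
  sc <- noise_free_scenario(soils = soils, suppression_slope = -8)
  design <- design_matrix_effects(c("LOW", "HIGH"), n_solvent = 2)
  batch <- simulate_batch(sc, design, cfg)
  eff <- compute_matrix_effects(batch$measurements, cfg, design,
                                reference_case = "solvent_standard")
  med <- tapply(eff$me_pct, eff$soil_id, median)
  expect_equal(unname(med["LOW"]), -8, tolerance = 1e-10)
  expect_equal(unname(med["HIGH"] - med["LOW"]), -32, tolerance = 1e-10)
})

test_that("measured matrix effects recover the injected truth within MC error", {
  cfg <- simulate_method_config(n_analytes = 10, n_ilis = 10, seed = 4,
                                n_negative_ilis = 0, n_negative_nsi = 0)
  sc <- sim_scenario(seed = 9, suppression_sd = 10)
  design <- design_matrix_effects("S4", n_spiked = 100, n_unspiked = 2,
                                  n_solvent = 100)
  batch <- simulate_batch(sc, design, cfg)
  eff <- compute_matrix_effects(batch$measurements, cfg, design,
                                reference_case = "solvent_standard")
  truth <- batch$truth$matrix_effects
  truth <- truth[truth$soil_id == "S4", ]
  got <- eff$me_pct[match(truth$species_id, eff$analyte_id)]
  keep <- !is.na(got)
  # area noise CV over 100 spiked and 100 reference injections
  se <- 100 * sc$noise_cv * sqrt(1 / 100 + 1 / 100)
  expect_true(all(abs(got[keep] - truth$me_pct[keep]) < 3 * se))
})

test_that("matrix-effect correlation between species decays with delta RT", {
  # many soils at one C_org act as repeated field draws; rank correlation
  # between species pairs must fall off with retention-time distance
  n_soils <- 80
  soils <- soil_table(c(sprintf("X%02d", seq_len(n_soils)), "SOLVENT"),
                      c_org_pct = c(rep(2, n_soils), 0))
  cfg <- simulate_method_config(n_analytes = 12, n_ilis = 12, seed = 4,
                                n_negative_ilis = 0, n_negative_nsi = 0)
  sc <- sim_scenario(soils = soils, seed = 77)
  design <- design_field("X01", n_replicates = 1)
  truth <- simulate_batch(sc, design, cfg)$truth

  me <- truth$matrix_effects[grepl("^X", truth$matrix_effects$soil_id), ]
  wide <- tidyr::pivot_wider(me, names_from = "species_id",
                             values_from = "me_pct")
  wide$soil_id <- NULL
  rts <- truth$species$expected_rt[match(names(wide),
                                         truth$species$species_id)]
  pairs <- t(utils::combn(seq_along(rts), 2))
  drt <- abs(rts[pairs[, 1]] - rts[pairs[, 2]])
  cors <- vapply(seq_len(nrow(pairs)), function(i) {
    cor(wide[[pairs[i, 1]]], wide[[pairs[i, 2]]])
  }, 0)
  expect_lt(cor(drt, cors, method = "spearman"), -0.5)
  # close pairs correlate strongly, distant pairs weakly
  expect_gt(mean(cors[drt < 0.5]), mean(cors[drt > 5]) + 0.3)
})

test_that("aged reference construction applies per-analyte losses", {
  cfg <- simulate_method_config(n_analytes = 10, n_ilis = 10, seed = 4,
                                n_negative_ilis = 0, n_negative_nsi = 0)
  none <- make_reference_aged(cfg, spike_ng_g = 10, aging_loss = 0)
  expect_true(all(none$native_conc$conc_ng_g == 10))

  fast <- make_reference_aged(
    cfg, spike_ng_g = 10,
    aging_loss = c(A001 = 0.93)
  )
  expect_equal(fast$native_conc$conc_ng_g[
    fast$native_conc$analyte_id == "A001"], 0.7)

  uniform <- make_reference_aged(cfg, spike_ng_g = 10, aging_loss = 0.07)
  expect_equal(median(uniform$native_conc$conc_ng_g), 9.3)

  expect_error(make_reference_aged(cfg, aging_loss = 1.2),
               class = "soilmrm_domain_error")
  expect_error(make_reference_aged(cfg, spike_ng_g = 0),
               class = "soilmrm_domain_error")
})

test_that("a pre-extraction ILIS spike with zero volume is a design error", {
  cfg <- simulate_method_config(n_analytes = 4, n_ilis = 4, seed = 4,
                                n_negative_ilis = 0, n_negative_nsi = 0,
                                ilis_spike_volume_uL = 0)
  sc <- noise_free_scenario()
  design <- design_field("S1", n_replicates = 1)
  expect_error(simulate_batch(sc, design, cfg),
               class = "soilmrm_design_error")
})
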