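test_that("the matrix-effect formula reproduces hand-computed cases", {
  expect_equal(matrix_effect(1000, 0, 1000), 0)
  expect_equal(matrix_effect(600, 100, 1000), -50)
  expect_equal(matrix_effect(1300, 100, 1000), 20)
  expect_error(matrix_effect(600, 100, 0), class = "soilmrm_domain_error")
})

test_that("the formula agrees with an independent arithmetic oracle", {
  set.seed(2)
  n <- 1e4
  sp <- runif(n, 0, 2000)
  un <- runif(n, 0, 500)
  ref <- runif(n, 1, 2000)
  oracle <- -100 * (1 - (sp - un) / ref)
  expect_equal(matrix_effect(sp, un, ref), oracle, tolerance = 1e-12)
})

test_that("the calibration matrix compared against itself gives exactly zero", {
  cfg <- simulate_method_config(n_analytes = 5, n_ilis = 5, seed = 4,
                                n_negative_ilis = 0, n_negative_nsi = 0)
  sc <- noise_free_scenario(suppression_sd = 0)
  design <- design_matrix_effects(c("S2", "S4"))
  batch <- simulate_batch(sc, design, cfg)
  eff <- compute_matrix_effects(batch$measurements, cfg, design,
                                reference_case = "s2_extract")
  self <- eff[eff$soil_id == "S2", ]
  expect_equal(self$me_pct, rep(0, nrow(self)))
  other <- eff[eff$soil_id == "S4", ]
  expect_true(all(other$me_pct < 0))
})

test_that("per-soil summaries report median, min and max", {
  eff <- tibble::tibble(
    analyte_id = c("a", "b", "c"), soil_id = "S3",
    reference_case = "solvent_standard", me_pct = c(0, -10, -20)
  )
  s <- summarize_matrix_effects(eff)
  expect_equal(s$median_me_pct, -10)
  expect_equal(s$min_me_pct, -20)
  expect_equal(s$max_me_pct, 0)
})

test_that("the global factor derivation applies grid, count and rounding", {
  mk <- function(me) {
    tibble::tibble(analyte_id = sprintf("A%03d", seq_along(me)),
                   soil_id = "S4", me_pct = me)
  }
  # covering -50% gives exactly 2
  eff <- mk(c(rep(-48, 5), rep(-20, 5), -60, -55, -52))
  out <- derive_global_factor(eff, max_exceedances = 3)
  expect_identical(out$suppression_pct, 50)
  expect_identical(out$factor, 2)
  expect_equal(out$n_exceeded, 3)
  expect_setequal(out$exceeded_analytes, c("A011", "A012", "A013"))

  # all suppressions >= -20% with more than three beyond the smaller grid
  # steps: s = 20, raw factor 1.25, rounded up to 1.5
  eff2 <- mk(c(-19, -18, -17, -16, -10, -6))
  out2 <- derive_global_factor(eff2, max_exceedances = 3)
  expect_equal(out2$suppression_pct, 20)
  expect_equal(out2$factor, 1.5)

  # no suppression at all: factor 1
  out3 <- derive_global_factor(mk(c(0, 5, 12)), max_exceedances = 3)
  expect_equal(out3$factor, 1)

  # nothing satisfies the constraint: largest grid value with a warning
  expect_warning(
    out4 <- derive_global_factor(mk(rep(-99, 10)), max_exceedances = 3,
                                 candidate_suppressions = c(10, 20)),
    "largest"
  )
  expect_false(out4$satisfied)
  expect_equal(out4$suppression_pct, 20)
})

test_that("the factor derivation is monotone in its inputs", {
  base <- tibble::tibble(
    analyte_id = sprintf("A%03d", 1:20), soil_id = "S4",
    me_pct = seq(-60, -3, length.out = 20)
  )
  f0 <- derive_global_factor(base, max_exceedances = 3)$factor
  # strengthening every suppression never lowers the factor
  worse <- base
  worse$me_pct <- worse$me_pct - 15
  f1 <- derive_global_factor(worse, max_exceedances = 3)$factor
  expect_gte(f1, f0)
  # allowing more exceedances never raises it
  f2 <- derive_global_factor(base, max_exceedances = 8)$factor
  expect_lte(f2, f0)
})

test_that("pooled and per-analyte exceedance counting differ as documented", {
  eff <- tibble::tibble(
    analyte_id = rep(c("a", "b"), each = 2),
    soil_id = rep(c("S3", "S4"), 2),
    me_pct = c(-55, -45, -10, -5)
  )
  # analyte a exceeds -20% in both soils but only one analyte exceeds at
  # all: per-analyte counting tolerates it at s = 20, pooled counting sees
  # two pairs and must climb to s = 50
  per <- derive_global_factor(eff, max_exceedances = 1,
                              candidate_suppressions = c(20, 50))
  pooled <- derive_global_factor(eff, max_exceedances = 1,
                                 candidate_suppressions = c(20, 50),
                                 mode = "pooled")
  expect_equal(per$suppression_pct, 20)
  expect_equal(per$n_exceeded, 1)
  expect_equal(pooled$suppression_pct, 50)
  expect_equal(pooled$n_exceeded, 1)
})

test_that("ILOQ takes the lowest level meeting both S/N minima inclusively", {
  cfg <- tiny_config()
  levels <- c(0.005, 0.01, 0.025, 0.05, 0.1, 0.25, 0.5, 1, 2.5)
  design <- design_solvent_series(levels)
  # S/N proportional to concentration: quantifier hits 10 exactly at 0.025
  rows <- lapply(seq_along(levels), function(i) {
    m <- tiny_measurements(design$sample_id[i])
    scale <- levels[i] / 0.025
    m$snr <- ifelse(m$transition_role == "quantifier", 10 * scale, 3 * scale)
    m
  })
  meas <- dplyr::bind_rows(rows)
  iloq <- determine_iloq(meas, cfg, design)
  expect_equal(iloq$iloq_ng_mL, c(0.025, 0.025))

  # qualifier never reaching its minimum leaves the ILOQ undetermined
  rows2 <- lapply(rows, function(m) {
    m$snr[m$transition_role == "qualifier"] <- 1
    m
  })
  iloq2 <- determine_iloq(dplyr::bind_rows(rows2), cfg, design)
  expect_true(all(is.na(iloq2$iloq_ng_mL)))
  expect_false(any(iloq2$determined))
})

test_that("MLOQ snaps to the calibration grid and scales with the factor", {
  cfg <- simulate_method_config(n_analytes = 6, n_ilis = 6, seed = 4,
                                n_negative_ilis = 0, n_negative_nsi = 0)
  sc <- noise_free_scenario()
  design <- design_calibration(cfg)
  batch <- simulate_batch(sc, design, cfg)

  m1 <- determine_mloq(batch$measurements, cfg, design, factor = 1)
  m2 <- determine_mloq(batch$measurements, cfg, design, factor = 2)
  expect_true(all(m1$base_mloq_ng_g %in% cfg$cal_levels))
  expect_equal(m1$corrected_mloq_ng_g, m1$base_mloq_ng_g)
  expect_equal(m2$corrected_mloq_ng_g, 2 * m2$base_mloq_ng_g)
  # the correction never reduces an MLOQ
  expect_true(all(m2$corrected_mloq_ng_g >= m2$base_mloq_ng_g))
  expect_error(determine_mloq(batch$measurements, cfg, design, factor = 0.5),
               class = "soilmrm_domain_error")
  expect_equal(unique(m2$factor_used), 2)
})
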