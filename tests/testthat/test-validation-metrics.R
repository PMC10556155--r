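test_that("relative recovery subtracts native residues exactly", {
  expect_equal(relative_recovery(2.5, 0, 2.5), 100)
  expect_equal(relative_recovery(3.0, 0.5, 2.5), 100)
  expect_equal(relative_recovery(2.0, 0, 2.5), 80)
  expect_error(relative_recovery(2, 0, 0), class = "soilmrm_domain_error")
  # invariance to a common native background
  bg <- runif(10, 0, 5)
  expect_equal(relative_recovery(2.5 + bg, bg, 2.5), rep(100, 10))
})

test_that("absolute recovery uses blank-subtracted raw responses", {
  expect_equal(absolute_recovery_quechers(1000, 1000, 0), 100)
  expect_equal(absolute_recovery_quechers(900, 1000, 100), 800 / 900 * 100,
               tolerance = 1e-12)
  expect_warning(out <- absolute_recovery_quechers(900, 100, 100))
  expect_true(is.na(out))
})

test_that("ILIS compensation separates relative from absolute recovery", {
  # the generator extracts 90% of the spike; a pre-extraction ILIS shares
  # the loss, so relative recovery returns 100% while the uncorrected
  # pre/post comparison returns the true 90%
  cfg <- simulate_method_config(n_analytes = 5, n_ilis = 5, seed = 4,
                                n_negative_ilis = 0, n_negative_nsi = 0)
  sc <- noise_free_scenario(extraction_recovery_mean = 0.90)
  design <- dplyr::bind_rows(
    design_calibration(cfg),
    design_recovery("S1", spike_level = 2.5, n_replicates = 1),
    design_matrix_effects("S1", spike_level = 2.5, n_spiked = 1)
  )
  batch <- simulate_batch(sc, design, cfg)
  ref <- ion_ratio_reference(batch$measurements, cfg, design)
  curves <- calibrate_batch(batch$measurements, cfg, design)
  flags <- check_identification(batch$measurements, cfg, design, ref)
  quant <- quantify_batch(batch$measurements, cfg, design, sc$soils,
                          curves, flags)

  sp <- quant[quant$role == "spike_pre_extraction", ]
  un <- quant[quant$role == "field", ]
  rel <- relative_recovery(
    sp$conc_raw_ng_g[order(sp$analyte_id)],
    un$conc_raw_ng_g[order(un$analyte_id)],
    2.5
  )
  expect_equal(rel, rep(100, 5), tolerance = 1e-9)

  # raw quantifier areas: pre-extraction spike vs post-extraction spike
  quantifier <- batch$measurements[
    batch$measurements$transition_role == "quantifier" &
      batch$measurements$species_id %in% cfg$analytes$analyte_id, ]
  pre_ids <- design$sample_id[design$role == "spike_pre_extraction"]
  post_ids <- design$sample_id[design$role == "spike_post_extraction"]
  pre <- quantifier[quantifier$sample_id %in% pre_ids, ]
  post <- quantifier[quantifier$sample_id %in% post_ids, ]
  abs_rec <- absolute_recovery_quechers(
    pre$peak_area[order(pre$species_id)],
    post$peak_area[order(post$species_id)]
  )
  expect_equal(abs_rec, rep(90, 5), tolerance = 1e-9)
})

test_that("precision tiers aggregate at the declared level", {
  expect_equal(precision(c(9, 10, 11), "intra_day")$rsd_pct, 10)
  expect_equal(precision(rep(4.2, 5), "instrumental")$rsd_pct, 0)

  vals <- c(1.0, 1.2, 2.0, 2.2, 3.0, 3.2)
  days <- rep(c("d1", "d2", "d3"), each = 2)
  p <- precision(vals, "inter_day", grouping = days)
  expect_equal(p$n_groups, 3)
  expect_equal(p$rsd_pct, 100 * sd(c(1.1, 2.1, 3.1)) / mean(c(1.1, 2.1, 3.1)))

  ops <- rep(c("p1", "p2"), each = 3)
  vp <- c(10, 11, 12, 10.5, 11.5, 12.5)
  pp <- precision(vp, "inter_person", grouping = ops)
  expect_equal(pp$rsd_pct, 100 * sd(c(11, 11.5)) / 11.25)

  expect_error(precision(c(1, 2), "intra_day"),
               class = "soilmrm_validation_error")
  expect_error(precision(vals, "inter_day", grouping = rep("d1", 6)),
               class = "soilmrm_validation_error")
  expect_warning(p0 <- precision(c(-1, 0, 1), "intra_day"))
  expect_true(is.na(p0$rsd_pct))
})

test_that("inter-day RSD on day means matches an ANOVA decomposition oracle", {
  set.seed(9)
  n_days <- 6
  n_rep <- 4
  tau <- 0.08   # between-day sd
  sig <- 0.05   # within-day sd
  day <- rep(sprintf("d%d", seq_len(n_days)), each = n_rep)
  vals <- 10 * exp(rep(rnorm(n_days, 0, tau), each = n_rep) +
                     rnorm(n_days * n_rep, 0, sig))
  inter <- precision(vals, "inter_day", grouping = day)$rsd_pct
  intra <- mean(tapply(vals, day, function(v) 100 * sd(v) / mean(v)))

  # oracle: day-mean variance from the one-way ANOVA mean squares
  fit <- stats::aov(vals ~ factor(day))
  ms <- summary(fit)[[1]]$`Mean Sq`
  # for a balanced design MS_between = n_rep * var(day means), so the
  # day-mean sd reconstructed from the ANOVA table must match exactly
  oracle_daymean_sd <- sqrt(ms[1] / n_rep)
  expect_equal(inter,
               100 * oracle_daymean_sd / mean(tapply(vals, day, mean)),
               tolerance = 1e-10)
  # day means absorb the within-day noise: the excess of inter- over
  # intra-day RSD is bounded by the injected between-day component
  expect_lt(inter, intra + 100 * tau * 3)
})

test_that("trueness deviations and band exceedances are reported", {
  measured <- tibble::tibble(
    analyte_id = c("a", "b", "c"),
    conc_ng_g = c(10, 9.3, 0.7)
  )
  out <- trueness_vs_reference(measured, 10)
  expect_equal(out$per_analyte$deviation_pct, c(0, -7, -93))
  expect_equal(out$per_analyte$within_band, c(TRUE, TRUE, FALSE))
  expect_equal(out$fraction_beyond, 1 / 3)
})

test_that("z-scores follow the median/MAD construction", {
  peers <- c(8, 9, 10, 11, 12)
  z0 <- z_scores(10, peers)
  expect_equal(z0$z, 0)
  expect_equal(z0$label, "good")

  z2 <- z_scores(13, peers)
  expect_equal(z2$z, 3 / (1.4826 * 1), tolerance = 1e-12)
  expect_equal(z2$label, "questionable")
  expect_true(z2$small_panel)

  zflat <- z_scores(5, c(7, 7, 7, 7))
  expect_true(is.na(zflat$z))
  expect_equal(zflat$label, "undefined")

  expect_error(z_scores(5, c(1, 2, 3)), class = "soilmrm_validation_error")

  # a conforming laboratory scores |z| < 2 about 95% of the time
  set.seed(4)
  hits <- replicate(400, {
    panel <- rnorm(30, 10, 1)
    abs(z_scores(rnorm(1, 10, 1), panel)$z) < 2
  })
  expect_gt(mean(hits), 0.90)
})
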