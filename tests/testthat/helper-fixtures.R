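# Shared fixtures and independent oracles, built in code at test time.

# A hand-written two-analyte / two-ILIS method: A1 has a structure-identical
# ILIS, A2 is measured as two separated stereoisomer peaks and quantified
# against IL2 (non-structure-identical, pre-assigned).
tiny_config <- function(assign_a2 = TRUE) {
  analytes <- tibble::tibble(
    analyte_id = c("A1", "A2"),
    name = c("alpha", "beta"),
    pesticide_class = c("fungicide", "herbicide"),
    polarity = c("positive", "positive"),
    expected_rt = c(10, 12),
    stereoisomer_group = c(NA, "A2"),
    si_ilis_id = c("IL1", NA),
    assigned_ilis_id = c(NA, if (assign_a2) "IL2" else NA)
  )
  ilis <- tibble::tibble(
    ilis_id = c("IL1", "IL2"),
    name = c("alpha-d5", "gamma-13C"),
    polarity = "positive",
    expected_rt = c(10.05, 11.5),
    tier_concentration = c(250, 750)
  )
  stereo <- tibble::tibble(
    species_id = c("A2a", "A2b"),
    analyte_id = c("A2", "A2")
  )
  species <- c("A1", "A2a", "A2b", "IL1", "IL2")
  transitions <- tibble::tibble(
    species_id = rep(species, each = 2),
    role = rep(c("quantifier", "qualifier"), length(species)),
    precursor_mz = rep(c(250, 300, 300, 255, 310), each = 2),
    product_mz = rep(c(120, 80, 150, 60, 95), times = 2)[seq_len(10)],
    polarity = "positive",
    expected_rt = rep(c(10, 11.85, 12.15, 10.05, 11.5), each = 2)
  )
  method_config(analytes, ilis, transitions, stereoisomers = stereo)
}

# Long-format measurement rows for one sample of the tiny config.
tiny_measurements <- function(sample_id = "s1",
                              areas = c(A1 = 5000, A2a = 3000, A2b = 2000,
                                        IL1 = 5000, IL2 = 10000),
                              qual_frac = 0.4, snr = 100, rt_shift = 0) {
  species <- names(areas)
  rts <- c(A1 = 10, A2a = 11.85, A2b = 12.15, IL1 = 10.05, IL2 = 11.5)
  tibble::tibble(
    sample_id = sample_id,
    species_id = rep(species, 2),
    transition_role = rep(c("quantifier", "qualifier"), each = length(species)),
    peak_area = c(unname(areas), unname(areas) * qual_frac),
    snr = rep(snr, 2 * length(species)),
    rt = rep(unname(rts[species]) + rt_shift, 2)
  )
}

# Independent weighted least-squares oracle: explicit normal equations,
# no call into the fitting path under test.
wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  beta <- solve(A, b)
  list(intercept = beta[1], slope = beta[2])
}

# Pooled-variance two-sample t statistic, coded from the textbook formula.
t_oracle <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# Noise-free scenario: every stochastic component switched off (individual
# components can be re-enabled through ...).
noise_free_scenario <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(noise_cv = 0, extraction_recovery_sd = 0, suppression_sd = 0,
         rt_jitter_sd_min = 0, seed = seed),
    list(...)
  )
  do.call(sim_scenario, args)
}

# One full-size stochastic validation batch, computed once per test run and
# shared between the end-to-end blocks.
.batch_cache <- new.env(parent = emptyenv())
full_validation_batch <- function() {
  if (is.null(.batch_cache$full)) {
    cfg <- simulate_method_config(seed = 101)
    sc <- sim_scenario(seed = 20260925)
    .batch_cache$full <- c(run_validation_batch(cfg, sc), list(config = cfg))
  }
  .batch_cache$full
}
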