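#' Simulate and process a complete validation batch
#'
#' One-call convenience wrapper used throughout the examples and tests:
#' builds a standard validation batch design (matrix-matched calibration
#' series, solvent dilution series, matrix-effect experiment, and
#' pre-/unspiked recovery preparations per evaluation soil), simulates it
#' under a scenario, and runs the full processing chain — calibration with
#' linearity review, ion-ratio reference, identification gating, ILOQ and
#' MLOQ determination, and quantification of the recovery samples.
#'
#' @param config A `method_config` with ILIS assignments resolved for the
#'   analytes to be quantified (structure-identical ones suffice).
#' @param scenario A `sim_scenario`.
#' @param recovery_soil_ids Soils receiving spiked/unspiked recovery
#'   preparations (default S1--S3).
#' @param me_soil_ids Soils of the matrix-effect experiment (default
#'   S1--S5; must include `cal_soil_id` for reference case ii).
#' @param spike_level Recovery spike level, ng/g dry weight.
#' @param n_replicates Replicates per recovery preparation.
#' @param cal_soil_id Calibration matrix.
#' @param mloq_factor Matrix correction factor for MLOQ; `NULL` derives it
#'   from the batch's case-ii matrix effects.
#' @return A list: `design`, `measurements`, `truth`, `curves`,
#'   `ratio_reference`, `id_flags`, `iloq`, `mloq`, `factor` (the
#'   correction-factor derivation when computed), `effects_case_ii`, and
#'   `quant` (quantified recovery samples).
#' @export
run_validation_batch <- function(config,
                                 scenario,
                                 recovery_soil_ids = c("S1", "S2", "S3"),
                                 me_soil_ids = c("S1", "S2", "S3", "S4", "S5"),
                                 spike_level = 2.5,
                                 n_replicates = 4,
                                 cal_soil_id = "S2",
                                 mloq_factor = NULL) {
  design <- dplyr::bind_rows(
    design_calibration(config, cal_soil_id = cal_soil_id),
    design_solvent_series(),
    design_matrix_effects(me_soil_ids, spike_level = spike_level),
    design_recovery(recovery_soil_ids, spike_level = spike_level,
                    n_replicates = n_replicates)
  )
  batch <- simulate_batch(scenario, design, config)
  meas <- batch$measurements

  ratio_ref <- ion_ratio_reference(meas, config, design,
                                   cal_soil_id = cal_soil_id)
  level_ok <- mloq_level_flags(meas, config, design, reference = ratio_ref,
                               cal_soil_id = cal_soil_id)
  curves <- calibrate_batch(meas, config, design, cal_soil_id = cal_soil_id,
                            level_ok = level_ok)
  id_flags <- check_identification(meas, config, design, ratio_ref,
                                   cal_soil_id = cal_soil_id)
  iloq <- determine_iloq(meas, config, design)

  effects_ii <- compute_matrix_effects(meas, config, design,
                                       reference_case = "s2_extract",
                                       cal_soil_id = cal_soil_id)
  factor_info <- NULL
  if (is.null(mloq_factor)) {
    factor_info <- derive_global_factor(effects_ii)
    mloq_factor <- factor_info$factor
  }
  mloq <- determine_mloq(meas, config, design, factor = mloq_factor,
                         reference = ratio_ref, cal_soil_id = cal_soil_id)
  quant <- quantify_batch(meas, config, design, scenario$soils, curves,
                          id_flags, mloq = mloq)
  list(
    design = design,
    measurements = meas,
    truth = batch$truth,
    curves = curves,
    ratio_reference = ratio_ref,
    id_flags = id_flags,
    iloq = iloq,
    mloq = mloq,
    factor = factor_info,
    effects_case_ii = effects_ii,
    quant = quant
  )
}
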