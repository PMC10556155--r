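#' Soil metadata table
#'
#' @param soil_id,c_org_pct,ph,water_content_pct,texture Vectors of equal
#'   length describing each soil: organic carbon content in percent (the
#'   matrix-complexity covariate driving electrospray ion suppression), pH,
#'   gravimetric water content in percent (0 for dried soil) and a free-text
#'   texture label. The pseudo-soil `"SOLVENT"` (zero organic carbon) stands
#'   for standards prepared in pure acidified acetonitrile.
#' @return A tibble of class `soil_table`.
#' @export
soil_table <- function(soil_id, c_org_pct, ph = NA_real_,
                       water_content_pct = 0, texture = NA_character_) {
  tbl <- tibble::tibble(
    soil_id = as.character(soil_id),
    c_org_pct = as.numeric(c_org_pct),
    ph = as.numeric(ph),
    water_content_pct = as.numeric(water_content_pct),
    texture = as.character(texture)
  )
  if (anyDuplicated(tbl$soil_id)) {
    abort_soilmrm("Duplicate soil_id.", "soilmrm_config_error")
  }
  if (any(tbl$c_org_pct < 0)) {
    abort_soilmrm("c_org_pct must be >= 0.", "soilmrm_validation_error")
  }
  if (any(tbl$water_content_pct < 0 | tbl$water_content_pct >= 100)) {
    abort_soilmrm("water_content_pct must be in [0, 100).",
                  "soilmrm_validation_error")
  }
  class(tbl) <- c("soil_table", class(tbl))
  tbl
}

#' Development soils used throughout the examples and simulations
#'
#' Five reference/standard soils spanning organic-carbon contents of about
#' 1--5% (the typical topsoil range the method targets), the calibration
#' matrix among them (`S2`, clayey loam), plus the `"SOLVENT"` pseudo-soil
#' for standards in pure solvent.
#'
#' @return A `soil_table` with soils S1--S5 and SOLVENT.
#' @export
default_soils <- function() {
  soil_table(
    soil_id = c("S1", "S2", "S3", "S4", "S5", "SOLVENT"),
    c_org_pct = c(0.89, 2.0, 5.1, 3.9, 2.8, 0),
    ph = c(7.4, 7.4, 3.6, 4.4, 6.8, NA),
    water_content_pct = 0,
    texture = c("loamy sand", "clayey loam", "forest sandy soil",
                "loamy soil", "loamy clay", "acetonitrile 2.5% FA")
  )
}

sample_roles <- c("cal_standard", "matrix_blank", "field",
                  "spike_pre_extraction", "spike_post_extraction",
                  "reference_aged")

new_design_rows <- function(sample_id, soil_id, role, nominal_level = NA_real_,
                            replicate_id = "r1", day_id = "d1",
                            operator_id = "op1", soil_mass_g = 5,
                            extract_volume_mL = 5, ilis_pre_extraction = TRUE) {
  tibble::tibble(
    sample_id = as.character(sample_id),
    soil_id = as.character(soil_id),
    role = as.character(role),
    nominal_level = as.numeric(nominal_level),
    replicate_id = as.character(replicate_id),
    day_id = as.character(day_id),
    operator_id = as.character(operator_id),
    soil_mass_g = as.numeric(soil_mass_g),
    extract_volume_mL = as.numeric(extract_volume_mL),
    ilis_pre_extraction = as.logical(ilis_pre_extraction)
  )
}

#' Validate a batch design
#'
#' A batch design lists one row per prepared sample: its soil, role in the
#' batch (calibration standard, matrix blank, pre-/post-extraction spike,
#' field sample, aged reference), nominal level where applicable,
#' replicate/day/operator labels, intake mass and extract volume, and
#' whether the ILIS MIX was spiked before extraction (so that it shares
#' extraction losses with the analytes) or into the final extract.
#'
#' @param design Tibble of sample records.
#' @param soils A `soil_table`; every `soil_id` in the design must resolve.
#' @return The validated design, invisibly.
#' @export
validate_batch_design <- function(design, soils) {
  assert_columns(design,
                 c("sample_id", "soil_id", "role", "nominal_level",
                   "replicate_id", "day_id", "operator_id", "soil_mass_g",
                   "extract_volume_mL", "ilis_pre_extraction"),
                 "batch design")
  if (anyDuplicated(design$sample_id)) {
    abort_soilmrm("Duplicate sample_id in batch design.",
                  "soilmrm_validation_error")
  }
  if (!all(design$role %in% sample_roles)) {
    abort_soilmrm(
      sprintf("Unknown sample role(s): %s",
              paste(setdiff(unique(design$role), sample_roles), collapse = ", ")),
      "soilmrm_validation_error"
    )
  }
  unknown <- setdiff(unique(design$soil_id), soils$soil_id)
  if (length(unknown) > 0L) {
    abort_soilmrm(sprintf("Design references unknown soil(s): %s",
                          paste(unknown, collapse = ", ")),
                  "soilmrm_reference_error")
  }
  needs_level <- design$role %in% c("cal_standard", "spike_pre_extraction",
                                    "spike_post_extraction")
  if (any(needs_level & is.na(design$nominal_level))) {
    abort_soilmrm("Calibration standards and spikes need a nominal_level.",
                  "soilmrm_validation_error")
  }
  if (any(design$soil_mass_g <= 0 & design$soil_id != "SOLVENT") ||
      any(design$extract_volume_mL <= 0)) {
    abort_soilmrm("soil_mass_g and extract_volume_mL must be positive.",
                  "soilmrm_validation_error")
  }
  invisible(design)
}

#' Batch-design builders
#'
#' Convenience constructors for the standard experiment layouts:
#'
#' * `design_calibration()` — matrix-matched calibration standards at every
#'   configured level (post-extraction spikes into a combined blank-matrix
#'   extract, ILIS added to the extract).
#' * `design_solvent_series()` — an ascending solvent-standard series used
#'   to determine instrumental limits of quantification.
#' * `design_matrix_effects()` — per soil, replicate extracts spiked with
#'   analytes + ILIS after extraction and extracts spiked with ILIS only,
#'   plus solvent standards at the same level (the two reference cases).
#' * `design_recovery()` — per soil, replicate pre-extraction spikes and
#'   unspiked samples; the basis for relative recoveries, intra-day
#'   precision and ILIS assignment.
#' * `design_reference_aged()` — repeated preparations of the aged
#'   reference soil across days/operators for trueness and inter-day,
#'   inter-person precision.
#' * `design_field()` — replicate preparations of field soils.
#'
#' Designs are plain tibbles and can be concatenated with
#' [dplyr::bind_rows()] as long as sample ids stay unique.
#'
#' @param config A `method_config` (supplies calibration levels).
#' @param cal_soil_id Soil used for matrix-matched calibration.
#' @param n_injections,n_spiked,n_unspiked,n_replicates Replicate counts.
#' @param soil_ids Soils to cover.
#' @param levels Solvent-series levels in ng/mL.
#' @param spike_level Spike level (ng/mL in the vial for post-extraction
#'   spikes; ng/g dry weight for pre-extraction spikes).
#' @param day_ids,operator_ids Labels for the repeated-preparation tiers.
#' @param soil_mass_g,extract_volume_mL Sample intake and extract volume.
#' @param prefix Sample-id prefix.
#' @return A batch-design tibble.
#' @name design_builders
NULL

#' @rdname design_builders
#' @export
design_calibration <- function(config, cal_soil_id = "S2", n_injections = 2,
                               soil_mass_g = 5, extract_volume_mL = 5) {
  levels <- config$cal_levels
  grid <- expand.grid(rep = seq_len(n_injections),
                      level = levels, KEEP.OUT.ATTRS = FALSE)
  new_design_rows(
    sample_id = sprintf("CAL_%s_L%02d_r%d", cal_soil_id,
                        match(grid$level, levels), grid$rep),
    soil_id = cal_soil_id,
    role = "cal_standard",
    nominal_level = grid$level,
    replicate_id = sprintf("r%d", grid$rep),
    soil_mass_g = soil_mass_g,
    extract_volume_mL = extract_volume_mL,
    ilis_pre_extraction = FALSE
  )
}

#' @rdname design_builders
#' @export
design_solvent_series <- function(levels = c(0.005, 0.01, 0.025, 0.05, 0.1,
                                             0.25, 0.5, 1, 2.5),
                                  n_injections = 1) {
  grid <- expand.grid(rep = seq_len(n_injections),
                      level = levels, KEEP.OUT.ATTRS = FALSE)
  new_design_rows(
    sample_id = sprintf("ILOQ_L%02d_r%d", match(grid$level, levels), grid$rep),
    soil_id = "SOLVENT",
    role = "cal_standard",
    nominal_level = grid$level,
    replicate_id = sprintf("r%d", grid$rep),
    soil_mass_g = 0,
    extract_volume_mL = 5,
    ilis_pre_extraction = FALSE
  )
}

#' @rdname design_builders
#' @export
design_matrix_effects <- function(soil_ids, spike_level = 2.5, n_spiked = 2,
                                  n_unspiked = 2, n_solvent = 2) {
  per_soil <- function(soil) {
    dplyr::bind_rows(
      new_design_rows(
        sample_id = sprintf("ME_%s_sp_r%d", soil, seq_len(n_spiked)),
        soil_id = soil, role = "spike_post_extraction",
        nominal_level = spike_level,
        replicate_id = sprintf("r%d", seq_len(n_spiked)),
        ilis_pre_extraction = FALSE
      ),
      new_design_rows(
        sample_id = sprintf("ME_%s_un_r%d", soil, seq_len(n_unspiked)),
        soil_id = soil, role = "matrix_blank",
        replicate_id = sprintf("r%d", seq_len(n_unspiked)),
        ilis_pre_extraction = FALSE
      )
    )
  }
  dplyr::bind_rows(
    dplyr::bind_rows(lapply(soil_ids, per_soil)),
    new_design_rows(
      sample_id = sprintf("ME_SOLVENT_std_r%d", seq_len(n_solvent)),
      soil_id = "SOLVENT", role = "cal_standard",
      nominal_level = spike_level,
      replicate_id = sprintf("r%d", seq_len(n_solvent)),
      soil_mass_g = 0,
      ilis_pre_extraction = FALSE
    )
  )
}

#' @rdname design_builders
#' @export
design_recovery <- function(soil_ids, spike_level = 2.5, n_replicates = 4,
                            day_ids = "d1", prefix = "REC") {
  per_day <- function(day) {
    per_soil <- function(soil) {
      dplyr::bind_rows(
        new_design_rows(
          sample_id = sprintf("%s_%s_%s_sp_r%d", prefix, soil, day,
                              seq_len(n_replicates)),
          soil_id = soil, role = "spike_pre_extraction",
          nominal_level = spike_level,
          replicate_id = sprintf("r%d", seq_len(n_replicates)),
          day_id = day
        ),
        new_design_rows(
          sample_id = sprintf("%s_%s_%s_un_r%d", prefix, soil, day,
                              seq_len(n_replicates)),
          soil_id = soil, role = "field",
          replicate_id = sprintf("r%d", seq_len(n_replicates)),
          day_id = day
        )
      )
    }
    dplyr::bind_rows(lapply(soil_ids, per_soil))
  }
  dplyr::bind_rows(lapply(day_ids, per_day))
}

#' @rdname design_builders
#' @export
design_reference_aged <- function(soil_id = "S2.1", n_replicates = 2,
                                  day_ids = c("d1", "d2", "d3"),
                                  operator_ids = "op1") {
  ops <- rep_len(operator_ids, length(day_ids))
  rows <- lapply(seq_along(day_ids), function(i) {
    new_design_rows(
      sample_id = sprintf("AGED_%s_%s_r%d", soil_id, day_ids[i],
                          seq_len(n_replicates)),
      soil_id = soil_id, role = "reference_aged",
      replicate_id = sprintf("r%d", seq_len(n_replicates)),
      day_id = day_ids[i], operator_id = ops[i]
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname design_builders
#' @export
design_field <- function(soil_ids, n_replicates = 4, prefix = "FLD") {
  rows <- lapply(soil_ids, function(soil) {
    new_design_rows(
      sample_id = sprintf("%s_%s_r%d", prefix, soil, seq_len(n_replicates)),
      soil_id = soil, role = "field",
      replicate_id = sprintf("r%d", seq_len(n_replicates))
    )
  })
  dplyr::bind_rows(rows)
}
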