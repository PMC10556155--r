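#' Instrumental limit of quantification from a solvent-standard series
#'
#' The ILOQ of an analyte is the lowest level of an ascending
#' solvent-standard dilution series whose quantifier and qualifier
#' transitions reach signal-to-noise ratios of at least the configured
#' minima (10 and 3 by default; boundary inclusive). Signal-to-noise is
#' averaged over replicate injections of a level; stereoisomer peaks
#' qualify through their strongest member.
#'
#' @param measurements,config,design Batch inputs; the series is taken
#'   from `cal_standard` samples of `solvent_soil_id`.
#' @param solvent_soil_id Pseudo-soil of the solvent series.
#' @return Tibble `analyte_id, iloq_ng_mL, determined`; `iloq_ng_mL` is
#'   `NA` where no level qualifies.
#' @export
determine_iloq <- function(measurements, config, design,
                           solvent_soil_id = "SOLVENT") {
  series <- design[design$role == "cal_standard" &
                     design$soil_id == solvent_soil_id, ]
  if (nrow(series) == 0L) {
    abort_soilmrm("No solvent-standard series in the design.",
                  "soilmrm_config_error")
  }
  qual_tbl <- level_qualification(measurements, config, series)
  per_analyte(qual_tbl, "iloq_ng_mL", require_ratio = FALSE)
}

#' Method limit of quantification from the matrix-matched series
#'
#' The base MLOQ of an analyte is the lowest matrix-matched calibration
#' level whose quantifier and qualifier signal-to-noise ratios meet the
#' configured minima and whose qualifier-to-quantifier ion ratio matches
#' the batch reference within its band tolerance. It snaps to the
#' calibration-level grid (no interpolation) and, at the nominal 5 g /
#' 5 mL design, reads identically in ng/mL of extract and ng/g dry
#' weight. The corrected MLOQ multiplies the base by the global matrix
#' correction factor (>= 1), which accounts for stronger ion suppression
#' in matrices other than the calibration soil.
#'
#' @param measurements,config,design Batch inputs.
#' @param factor Global matrix correction factor (default: the configured
#'   one; see [derive_global_factor()]).
#' @param reference Batch ion-ratio reference (default: computed from the
#'   same standards via [ion_ratio_reference()]).
#' @param cal_soil_id Soil of the matrix-matched standards.
#' @return Tibble `analyte_id, base_mloq_ng_g, corrected_mloq_ng_g,
#'   factor_used, determined`.
#' @export
determine_mloq <- function(measurements, config, design, factor = NULL,
                           reference = NULL, cal_soil_id = "S2") {
  factor <- factor %||% config$params$global_matrix_correction_factor
  if (factor < 1) {
    abort_soilmrm("The matrix correction factor must be >= 1.",
                  "soilmrm_domain_error")
  }
  series <- design[design$role == "cal_standard" &
                     design$soil_id == cal_soil_id, ]
  if (nrow(series) == 0L) {
    abort_soilmrm("No matrix-matched calibration series in the design.",
                  "soilmrm_config_error")
  }
  reference <- reference %||%
    ion_ratio_reference(measurements, config, design,
                        cal_soil_id = cal_soil_id)
  qual_tbl <- level_qualification(measurements, config, series, reference)
  out <- per_analyte(qual_tbl, "base_mloq_ng_g", require_ratio = TRUE)
  out$corrected_mloq_ng_g <- out$base_mloq_ng_g * factor
  out$factor_used <- factor
  out
}

#' Per-level MLOQ qualification flags for linearity review
#'
#' Convenience wrapper returning, per analyte and calibration level,
#' whether the level meets the signal-to-noise and ion-ratio rules — the
#' flags that constrain the lower edge of the linear range in
#' [calibrate_batch()].
#'
#' @inheritParams determine_mloq
#' @return Tibble `analyte_id, nominal, ok`.
#' @export
mloq_level_flags <- function(measurements, config, design,
                             reference = NULL, cal_soil_id = "S2") {
  series <- design[design$role == "cal_standard" &
                     design$soil_id == cal_soil_id, ]
  reference <- reference %||%
    ion_ratio_reference(measurements, config, design,
                        cal_soil_id = cal_soil_id)
  q <- level_qualification(measurements, config, series, reference)
  tibble::tibble(analyte_id = q$analyte_id, nominal = q$nominal,
                 ok = q$snr_ok & q$ratio_ok)
}

# Per analyte x level: mean S/N of quantifier and qualifier (stereoisomer
# peaks: strongest member), plus ion-ratio conformity against `reference`.
level_qualification <- function(measurements, config, series,
                                reference = NULL) {
  meas <- measurements[measurements$sample_id %in% series$sample_id, ]
  map <- dplyr::bind_rows(lapply(config$analytes$analyte_id, function(a) {
    tibble::tibble(analyte_id = a, species_id = analyte_species(config, a))
  }))
  m <- dplyr::inner_join(meas, map, by = "species_id")
  m$nominal <- series$nominal_level[match(m$sample_id, series$sample_id)]

  snr <- dplyr::summarise(
    dplyr::group_by(m, .data$analyte_id, .data$nominal, .data$sample_id,
                    .data$transition_role),
    snr = max(.data$snr),
    area = sum(.data$peak_area),
    .groups = "drop"
  )
  snr <- dplyr::summarise(
    dplyr::group_by(snr, .data$analyte_id, .data$nominal,
                    .data$transition_role),
    snr = mean(.data$snr),
    area = mean(.data$area),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(snr, names_from = "transition_role",
                             values_from = c("snr", "area"))
  p <- config_params_of(config)
  wide$snr_ok <- wide$snr_quantifier >= p$snr_quant_min &
    wide$snr_qualifier >= p$snr_qual_min

  if (!is.null(reference)) {
    ref <- reference$mean_ratio[match(wide$analyte_id,
                                      reference$analyte_id)]
    tol <- rep(NA_real_, length(ref))
    has <- !is.na(ref) & ref > 0
    tol[has] <- ratio_tolerance(ref[has])
    obs <- ifelse(wide$area_quantifier > 0,
                  wide$area_qualifier / wide$area_quantifier, NA_real_)
    wide$ratio_ok <- has & !is.na(obs) &
      abs(obs - ref) / ref * 100 <= tol
  } else {
    wide$ratio_ok <- TRUE
  }
  wide
}

config_params_of <- function(config) config$params

per_analyte <- function(qual_tbl, value_col, require_ratio) {
  qual_tbl$ok <- if (require_ratio) {
    qual_tbl$snr_ok & qual_tbl$ratio_ok
  } else {
    qual_tbl$snr_ok
  }
  out <- dplyr::summarise(
    dplyr::group_by(qual_tbl, .data$analyte_id),
    value = if (any(.data$ok)) min(.data$nominal[.data$ok]) else NA_real_,
    .groups = "drop"
  )
  out$determined <- !is.na(out$value)
  names(out)[names(out) == "value"] <- value_col
  out[, c("analyte_id", value_col, "determined")]
}
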