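#' Enumerate ILIS candidates for an analyte without a structure-identical
#' standard
#'
#' Candidates must share the analyte's ionisation polarity. In positive
#' mode the pool is additionally restricted to ILIS eluting within
#' `rt_window` minutes of the analyte (boundary inclusive), because the
#' matrix-effect compensation an ILIS provides decays with retention-time
#' distance; in negative mode no retention-time restriction is applied
#' (the pool is small to begin with).
#'
#' @param config A `method_config`.
#' @param analyte_id An analyte without `si_ilis_id`.
#' @param rt_window Retention-time window in minutes (default 2).
#' @return Tibble `analyte_id, ilis_id, delta_rt` (analyte RT minus ILIS
#'   RT), one row per candidate.
#' @export
enumerate_candidates <- function(config, analyte_id, rt_window = 2) {
  an <- config$analytes[config$analytes$analyte_id == analyte_id, ]
  if (nrow(an) != 1L) {
    abort_soilmrm(sprintf("Unknown analyte: %s", analyte_id),
                  "soilmrm_reference_error")
  }
  if (!is.na(an$si_ilis_id)) {
    abort_soilmrm(
      sprintf("Analyte %s has a structure-identical ILIS; it is never reassigned.",
              analyte_id),
      "soilmrm_config_error"
    )
  }
  pool <- config$ilis[config$ilis$polarity == an$polarity, ]
  delta <- an$expected_rt - pool$expected_rt
  if (an$polarity == "positive") {
    keep <- abs(delta) <= rt_window
    pool <- pool[keep, ]
    delta <- delta[keep]
  }
  if (nrow(pool) == 0L) {
    abort_soilmrm(
      sprintf("No ILIS candidate for analyte %s (polarity %s).",
              analyte_id, an$polarity),
      "soilmrm_assignment_impossible_error"
    )
  }
  tibble::tibble(analyte_id = analyte_id, ilis_id = pool$ilis_id,
                 delta_rt = delta)
}

#' Relative recoveries of every analyte-ILIS candidate pair
#'
#' For each candidate pair the evaluation soils are quantified as if the
#' candidate were the analyte's ILIS: a 1/x-weighted matrix-matched
#' calibration is fitted with the candidate's PARs, the pre-extraction
#' spiked and unspiked preparations of each soil are quantified against
#' it, and the relative recovery is `100 * (conc_spiked - conc_unspiked) /
#' spike_level` (the spiked-minus-unspiked construction keeps native
#' residues from biasing selection). Replicates are averaged per soil.
#'
#' @param measurements,config,design,soils Batch inputs covering a
#'   matrix-matched calibration series plus spiked (role
#'   `spike_pre_extraction`) and unspiked (role `field`) preparations of
#'   the evaluation soils.
#' @param candidates Tibble from [enumerate_candidates()] (stacked over
#'   analytes).
#' @param spike_level Evaluation spike level in ng/g dry weight
#'   (default 2.5).
#' @param cal_soil_id Calibration matrix.
#' @return Tibble `analyte_id, ilis_id, delta_rt, soil_id, recovery_pct`.
#' @export
candidate_recoveries <- function(measurements, config, design, soils,
                                 candidates, spike_level = 2.5,
                                 cal_soil_id = "S2") {
  eval_design <- design[design$role %in% c("spike_pre_extraction", "field"), ]
  cal <- design[design$role == "cal_standard" &
                  design$soil_id == cal_soil_id, ]
  meas_cal <- measurements[measurements$sample_id %in% cal$sample_id, ]
  meas_eval <- measurements[measurements$sample_id %in%
                              eval_design$sample_id, ]
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    aid <- candidates$analyte_id[i]
    iid <- candidates$ilis_id[i]
    override <- stats::setNames(iid, aid)
    cal_pars <- compute_par(meas_cal, config, analyte_ids = aid,
                            ilis_override = override)
    cal_pars <- cal_pars[cal_pars$par_defined, ]
    cal_pars$nominal <- cal$nominal_level[match(cal_pars$sample_id,
                                                cal$sample_id)]
    if (length(unique(cal_pars$nominal)) < 5L) {
      return(NULL)
    }
    fit <- fit_calibration(cal_pars$nominal, cal_pars$par)
    pars <- compute_par(meas_eval, config, analyte_ids = aid,
                        ilis_override = override)
    pars <- pars[pars$par_defined, ]
    d_idx <- match(pars$sample_id, eval_design$sample_id)
    pars$soil_id <- eval_design$soil_id[d_idx]
    pars$role <- eval_design$role[d_idx]
    water <- soils$water_content_pct[match(pars$soil_id, soils$soil_id)]
    dm <- dry_weight_equivalent(eval_design$soil_mass_g[d_idx], water)
    pars$conc_ng_g <- (pars$par - fit$intercept) / fit$slope *
      eval_design$extract_volume_mL[d_idx] / dm
    per_soil <- dplyr::summarise(
      dplyr::group_by(pars, .data$soil_id, .data$role),
      conc = mean(.data$conc_ng_g), .groups = "drop"
    )
    wide <- tidyr::pivot_wider(per_soil, names_from = "role",
                               values_from = "conc")
    if (!"field" %in% names(wide)) wide$field <- 0
    wide$field[is.na(wide$field)] <- 0
    tibble::tibble(
      analyte_id = aid,
      ilis_id = iid,
      delta_rt = candidates$delta_rt[i],
      soil_id = wide$soil_id,
      recovery_pct = 100 * (wide$spike_pre_extraction - wide$field) /
        spike_level
    )
  })
  dplyr::bind_rows(rows)
}

#' Score candidates and select one ILIS per analyte
#'
#' Selection hierarchy: maximise the number of evaluation soils whose
#' relative recovery falls inside the acceptance band (70--120% by
#' default); break ties by minimising the recovery dispersion
#' `sum(|recovery - 100|)` across soils, then by minimising `|delta RT|`,
#' then lexicographically by ILIS id so the assignment is deterministic.
#' The full ranking of every candidate is returned as an audit trail.
#'
#' @param recoveries Output of [candidate_recoveries()].
#' @param band Acceptance band in percent (default `c(70, 120)`).
#' @return A list: `assignments` (one row per analyte: chosen ILIS,
#'   `n_soils_in_band`, `n_soils`, `dispersion`, `delta_rt`,
#'   `all_in_band`) and `audit` (every candidate with its rank).
#' @export
score_and_select <- function(recoveries, band = c(70, 120)) {
  scored <- dplyr::summarise(
    dplyr::group_by(recoveries, .data$analyte_id, .data$ilis_id,
                    .data$delta_rt),
    n_soils = dplyr::n(),
    n_soils_in_band = sum(.data$recovery_pct >= band[1] &
                            .data$recovery_pct <= band[2]),
    dispersion = sum(abs(.data$recovery_pct - 100)),
    .groups = "drop"
  )
  scored <- dplyr::arrange(
    dplyr::group_by(scored, .data$analyte_id),
    dplyr::desc(.data$n_soils_in_band), .data$dispersion,
    abs(.data$delta_rt), .data$ilis_id,
    .by_group = TRUE
  )
  scored <- dplyr::mutate(scored, rank = dplyr::row_number())
  scored <- dplyr::ungroup(scored)
  assignments <- scored[scored$rank == 1L, ]
  assignments$all_in_band <- assignments$n_soils_in_band ==
    assignments$n_soils
  list(
    assignments = assignments[, c("analyte_id", "ilis_id",
                                  "n_soils_in_band", "n_soils",
                                  "dispersion", "delta_rt", "all_in_band")],
    audit = scored
  )
}

#' Freeze ILIS assignments into a method configuration
#'
#' Writes the selected ILIS of each analyte into `assigned_ilis_id`.
#' Analytes with a structure-identical ILIS are never touched. When an
#' analyte already carries a different assignment, the change is reported
#' in the `assignment_diff` attribute (and a message) instead of being
#' applied silently; pass `overwrite = TRUE` to accept the new selection.
#'
#' @param config A `method_config`.
#' @param assignments The `assignments` element of [score_and_select()]
#'   (or any tibble with `analyte_id`, `ilis_id`).
#' @param overwrite Replace existing differing assignments (default
#'   `FALSE`).
#' @return The updated, revalidated `method_config`, with an
#'   `assignment_diff` attribute listing analytes whose previous and new
#'   assignment differ.
#' @export
assign_ilis <- function(config, assignments, overwrite = FALSE) {
  an <- config$analytes
  idx <- match(assignments$analyte_id, an$analyte_id)
  if (anyNA(idx)) {
    abort_soilmrm("Assignment references unknown analyte.",
                  "soilmrm_reference_error")
  }
  si <- !is.na(an$si_ilis_id[idx])
  if (any(si)) {
    abort_soilmrm(
      sprintf("Refusing to reassign analytes with structure-identical ILIS: %s",
              paste(assignments$analyte_id[si], collapse = ", ")),
      "soilmrm_config_error"
    )
  }
  prev <- an$assigned_ilis_id[idx]
  differs <- !is.na(prev) & prev != assignments$ilis_id
  diff_tbl <- tibble::tibble(
    analyte_id = assignments$analyte_id[differs],
    previous_ilis_id = prev[differs],
    new_ilis_id = assignments$ilis_id[differs]
  )
  apply_rows <- if (overwrite) rep(TRUE, length(idx)) else !differs
  an$assigned_ilis_id[idx[apply_rows]] <- assignments$ilis_id[apply_rows]
  if (nrow(diff_tbl) > 0L && !overwrite) {
    message(nrow(diff_tbl), " analyte(s) kept their previous assignment; ",
            "see attr(, 'assignment_diff') and use overwrite = TRUE to accept.")
  }
  config$analytes <- an
  config <- validate_method_config(config)
  attr(config, "assignment_diff") <- diff_tbl
  config
}
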