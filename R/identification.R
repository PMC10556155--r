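#' Ion-ratio tolerance bands (Directive 2002/657/EC)
#'
#' The allowed relative deviation of an observed qualifier-to-quantifier
#' ion ratio from its reference value depends on the size of the reference
#' ratio: abundant qualifiers are held to tighter tolerances.
#'
#' | reference ratio | tolerance |
#' |---|---|
#' | > 0.5 | ±20% |
#' | > 0.2 to 0.5 | ±25% |
#' | > 0.1 to 0.2 | ±30% |
#' | <= 0.1 | ±50% |
#'
#' Band boundaries are closed on the lower band (a ratio of exactly 0.5
#' gets ±25%); the boundary convention is configurable through
#' `boundaries`.
#'
#' @param mean_ratio Positive reference ratio(s).
#' @param boundaries `"lower"` (default) assigns a boundary value to the
#'   band below it; `"upper"` to the band above.
#' @return Tolerance in percent, vectorised over `mean_ratio`.
#' @examples
#' ratio_tolerance(c(0.8, 0.5, 0.15, 0.05))
#' @export
ratio_tolerance <- function(mean_ratio, boundaries = c("lower", "upper")) {
  boundaries <- match.arg(boundaries)
  if (any(!is.finite(mean_ratio)) || any(mean_ratio <= 0)) {
    abort_soilmrm("mean_ratio must be positive.", "soilmrm_domain_error")
  }
  cuts <- c(0.1, 0.2, 0.5)
  tols <- c(50, 30, 25, 20)
  idx <- if (boundaries == "lower") {
    findInterval(mean_ratio, cuts, left.open = TRUE) + 1L
  } else {
    findInterval(mean_ratio, cuts) + 1L
  }
  tols[idx]
}

#' Batch reference ion ratios from calibration standards
#'
#' The reference qualifier-to-quantifier ratio of each analyte is the mean
#' ratio over all matrix-matched calibration standards of the sequence in
#' which both transitions were detected (area > 0); stereoisomer peaks are
#' summed per transition before the ratio is formed.
#'
#' @param measurements,config,design Batch inputs.
#' @param cal_soil_id Soil of the matrix-matched standards.
#' @return Tibble `analyte_id, mean_ratio, n_standards`; `mean_ratio` is
#'   `NA` for analytes whose qualifier was never detected.
#' @export
ion_ratio_reference <- function(measurements, config, design,
                                cal_soil_id = "S2") {
  cal_ids <- design$sample_id[design$role == "cal_standard" &
                                design$soil_id == cal_soil_id]
  meas <- measurements[measurements$sample_id %in% cal_ids, ]
  rat <- analyte_ratios(meas, config)
  rat <- rat[rat$quant_area > 0 & rat$qual_area > 0, ]
  dplyr::summarise(
    dplyr::group_by(rat, .data$analyte_id),
    mean_ratio = mean(.data$qual_area / .data$quant_area),
    n_standards = dplyr::n(),
    .groups = "drop"
  )
}

# per sample x analyte: summed quantifier/qualifier areas and the observed
# quantifier retention time (area-weighted over stereoisomer peaks)
analyte_ratios <- function(measurements, config, analyte_ids = NULL) {
  an <- config$analytes
  analyte_ids <- analyte_ids %||% an$analyte_id
  map <- dplyr::bind_rows(lapply(analyte_ids, function(a) {
    tibble::tibble(analyte_id = a, species_id = analyte_species(config, a))
  }))
  m <- dplyr::inner_join(measurements, map, by = "species_id")
  quant <- m[m$transition_role == "quantifier", ]
  qual <- m[m$transition_role == "qualifier", ]
  q1 <- dplyr::summarise(
    dplyr::group_by(quant, .data$sample_id, .data$analyte_id),
    quant_area = sum(.data$peak_area),
    rt = ifelse(sum(.data$peak_area) > 0,
                sum(.data$rt * .data$peak_area) / sum(.data$peak_area),
                mean(.data$rt)),
    .groups = "drop"
  )
  q2 <- dplyr::summarise(
    dplyr::group_by(qual, .data$sample_id, .data$analyte_id),
    qual_area = sum(.data$peak_area),
    .groups = "drop"
  )
  dplyr::left_join(q1, q2, by = c("sample_id", "analyte_id"))
}

#' Identification gating by retention time and ion ratio
#'
#' A candidate detection is reportable only if (i) its observed retention
#' time matches the analyte's retention time in the simultaneously acquired
#' matrix-matched calibration standards within `rt_tol` minutes (boundary
#' inclusive) and (ii) its qualifier-to-quantifier ion ratio deviates from
#' the batch reference ratio by no more than the Directive 2002/657/EC band
#' tolerance (see [ratio_tolerance()]). A missing qualifier (area 0) fails
#' the ratio gate with reason `"qualifier_absent"`. Detections failing
#' either gate are reported as detected-but-unconfirmed downstream, not
#' dropped.
#'
#' @param measurements,config,design Batch inputs.
#' @param reference Output of [ion_ratio_reference()] for the same batch.
#' @param rt_tol Retention-time tolerance in minutes (default: configured
#'   `rt_match_tol_min`).
#' @param rt_reference `"batch_mean"` compares against the mean observed
#'   standard retention time over the sequence; `"nearest"` uses the
#'   standard nearest in injection order and requires an `injection_order`
#'   column in the design.
#' @param cal_soil_id Soil of the matrix-matched standards.
#' @param sample_ids Samples to gate (default: every non-calibration
#'   sample).
#' @return Tibble with one row per sample x analyte: observed and reference
#'   retention times and ratios, the applied tolerance, `rt_pass`,
#'   `ratio_pass`, `id_pass` and a `reason` code.
#' @export
check_identification <- function(measurements, config, design, reference,
                                 rt_tol = NULL,
                                 rt_reference = c("batch_mean", "nearest"),
                                 cal_soil_id = "S2", sample_ids = NULL) {
  rt_reference <- match.arg(rt_reference)
  rt_tol <- rt_tol %||% config$params$rt_match_tol_min
  cal <- design[design$role == "cal_standard" &
                  design$soil_id == cal_soil_id, ]
  if (nrow(cal) == 0L) {
    abort_soilmrm("No calibration standards to reference against.",
                  "soilmrm_insufficient_calibration_error")
  }
  if (rt_reference == "nearest" && !"injection_order" %in% names(design)) {
    abort_soilmrm(
      "rt_reference = 'nearest' needs an injection_order column in the design.",
      "soilmrm_config_error"
    )
  }
  sample_ids <- sample_ids %||%
    design$sample_id[design$role != "cal_standard"]

  rat_cal <- analyte_ratios(
    measurements[measurements$sample_id %in% cal$sample_id, ], config)
  rat_cal <- rat_cal[rat_cal$quant_area > 0, ]
  rat_smp <- analyte_ratios(
    measurements[measurements$sample_id %in% sample_ids, ], config)

  if (rt_reference == "batch_mean") {
    rt_ref <- dplyr::summarise(
      dplyr::group_by(rat_cal, .data$analyte_id),
      rt_reference = mean(.data$rt), .groups = "drop"
    )
    rat_smp <- dplyr::left_join(rat_smp, rt_ref, by = "analyte_id")
  } else {
    ord <- stats::setNames(design$injection_order, design$sample_id)
    rat_cal$injection_order <- ord[rat_cal$sample_id]
    rat_smp$injection_order <- ord[rat_smp$sample_id]
    rat_smp$rt_reference <- vapply(seq_len(nrow(rat_smp)), function(i) {
      cand <- rat_cal[rat_cal$analyte_id == rat_smp$analyte_id[i], ]
      if (nrow(cand) == 0L) return(NA_real_)
      cand$rt[which.min(abs(cand$injection_order -
                              rat_smp$injection_order[i]))]
    }, 0)
    rat_smp$injection_order <- NULL
  }

  out <- dplyr::left_join(rat_smp, reference, by = "analyte_id")
  out$delta_rt <- out$rt - out$rt_reference
  # boundary inclusive, robust to floating-point representation of the
  # tolerance (a shift of exactly rt_tol passes)
  out$rt_pass <- !is.na(out$delta_rt) &
    abs(out$delta_rt) <= rt_tol + 1e-9
  out$ratio_observed <- ifelse(out$quant_area > 0,
                               out$qual_area / out$quant_area, NA_real_)
  out$ratio_tolerance_pct <- NA_real_
  has_ref <- !is.na(out$mean_ratio) & out$mean_ratio > 0
  out$ratio_tolerance_pct[has_ref] <- ratio_tolerance(out$mean_ratio[has_ref])
  ratio_dev <- abs(out$ratio_observed - out$mean_ratio) / out$mean_ratio
  out$ratio_pass <- !is.na(out$ratio_observed) & out$qual_area > 0 &
    !is.na(out$mean_ratio) &
    ratio_dev * 100 <= out$ratio_tolerance_pct
  out$reason <- dplyr::case_when(
    out$quant_area <= 0 ~ "not_detected",
    is.na(out$mean_ratio) ~ "no_reference_ratio",
    out$qual_area <= 0 ~ "qualifier_absent",
    !out$ratio_pass & !out$rt_pass ~ "ratio_and_rt",
    !out$ratio_pass ~ "ratio_outside_band",
    !out$rt_pass ~ "rt_mismatch",
    TRUE ~ "ok"
  )
  out$id_pass <- out$rt_pass & out$ratio_pass
  names(out)[names(out) == "mean_ratio"] <- "ratio_reference"
  out[, c("sample_id", "analyte_id", "quant_area", "qual_area", "rt",
          "rt_reference", "delta_rt", "rt_pass", "ratio_observed",
          "ratio_reference", "ratio_tolerance_pct", "ratio_pass",
          "id_pass", "reason")]
}
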