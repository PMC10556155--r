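#' Quantify a batch against its calibration
#'
#' Converts gated peak-area ratios to concentrations in ng/g dry weight and
#' applies the censoring rules. For each sample x analyte the extract
#' concentration is `(PAR - intercept) / slope` in ng/mL; the soil
#' concentration is `extract_conc * extract_volume_mL /
#' dry_weight_equivalent(soil_mass_g, water_content)`. A result is reported
#' as `quantified` only when the identification gates pass, the extract
#' concentration lies inside the analyte's linear range, and the soil
#' concentration is at or above the applied MLOQ; otherwise the record is
#' censored as `unconfirmed`, `above_linear_range` (re-dilution flag),
#' `below_mloq`, or `ilis_missing` (undefined PAR).
#'
#' @param measurements,config,design Batch inputs.
#' @param soils A `soil_table` (supplies water content per soil).
#' @param curves A `calibration_table` from [calibrate_batch()].
#' @param id_flags Output of [check_identification()] covering the samples
#'   to quantify.
#' @param mloq Output of [determine_mloq()]; analytes with undetermined
#'   MLOQ are censored `below_mloq` unless quantified above their linear
#'   low end, in which case the linear low end acts as the floor. May be
#'   `NULL`, in which case only the linear range censors.
#' @param sample_ids Samples to quantify (default: all field,
#'   pre-extraction spike, aged-reference and matrix-blank samples).
#' @return Tibble with one row per sample x analyte: `conc_extract_ng_mL`,
#'   `conc_ng_g`, `censor` (factor of `quantified, below_mloq,
#'   above_linear_range, unconfirmed, ilis_missing`), `mloq_applied`.
#'   `conc_ng_g` is `NA` unless `censor == "quantified"`; the uncensored
#'   value is kept in `conc_raw_ng_g` for diagnostics.
#' @export
quantify_batch <- function(measurements, config, design, soils, curves,
                           id_flags, mloq = NULL, sample_ids = NULL) {
  sample_ids <- sample_ids %||%
    design$sample_id[design$role %in% c("field", "spike_pre_extraction",
                                        "spike_post_extraction",
                                        "reference_aged", "matrix_blank")]
  bad <- curves$fitted & !is.na(curves$slope) & curves$slope <= 0
  if (any(bad)) {
    abort_soilmrm(
      sprintf("Non-positive calibration slope for analyte(s): %s",
              paste(curves$analyte_id[bad], collapse = ", ")),
      "soilmrm_invalid_curve_error"
    )
  }

  meas <- measurements[measurements$sample_id %in% sample_ids, ]
  pars <- compute_par(meas, config,
                      analyte_ids = curves$analyte_id[curves$fitted])
  idx <- match(pars$analyte_id, curves$analyte_id)
  pars$slope <- curves$slope[idx]
  pars$intercept <- curves$intercept[idx]
  pars$linear_low <- curves$linear_low[idx]
  pars$linear_high <- curves$linear_high[idx]

  d_idx <- match(pars$sample_id, design$sample_id)
  water <- soils$water_content_pct[match(design$soil_id[d_idx],
                                         soils$soil_id)]
  dm <- dry_weight_equivalent(design$soil_mass_g[d_idx], water)
  pars$conc_extract_ng_mL <- (pars$par - pars$intercept) / pars$slope
  pars$conc_raw_ng_g <- pars$conc_extract_ng_mL *
    design$extract_volume_mL[d_idx] / dm

  flags <- id_flags[, c("sample_id", "analyte_id", "id_pass")]
  pars <- dplyr::left_join(pars, flags, by = c("sample_id", "analyte_id"))
  pars$id_pass[is.na(pars$id_pass)] <- FALSE

  if (!is.null(mloq)) {
    m_idx <- match(pars$analyte_id, mloq$analyte_id)
    pars$mloq_applied <- mloq$corrected_mloq_ng_g[m_idx]
  } else {
    pars$mloq_applied <- NA_real_
  }
  floor_ng_g <- ifelse(is.na(pars$mloq_applied),
                       pars$linear_low, pars$mloq_applied)

  pars$censor <- dplyr::case_when(
    !pars$par_defined ~ "ilis_missing",
    !pars$id_pass ~ "unconfirmed",
    pars$conc_extract_ng_mL > pars$linear_high ~ "above_linear_range",
    pars$conc_raw_ng_g < floor_ng_g |
      pars$conc_extract_ng_mL < pars$linear_low ~ "below_mloq",
    TRUE ~ "quantified"
  )
  pars$conc_ng_g <- ifelse(pars$censor == "quantified",
                           pars$conc_raw_ng_g, NA_real_)
  pars$soil_id <- design$soil_id[d_idx]
  pars$role <- design$role[d_idx]
  pars$replicate_id <- design$replicate_id[d_idx]
  pars$day_id <- design$day_id[d_idx]
  pars$operator_id <- design$operator_id[d_idx]
  pars[, c("sample_id", "soil_id", "role", "replicate_id", "day_id",
           "operator_id", "analyte_id", "par", "conc_extract_ng_mL",
           "conc_raw_ng_g", "conc_ng_g", "censor", "mloq_applied",
           "linear_low", "linear_high")]
}

#' Average replicate preparations
#'
#' Replicates are quantified individually and averaged at the reporting
#' boundary: per group (default analyte x soil), the reported
#' concentration is the mean over replicates with `censor == "quantified"`.
#' A group with no quantified replicate keeps the modal censor state of its
#' replicates.
#'
#' @param records Output of [quantify_batch()].
#' @param by Grouping columns (default `c("analyte_id", "soil_id")`).
#' @return One row per group: `conc_ng_g`, `n_quantified`, `n_replicates`,
#'   `censor`, `mloq_applied`.
#' @export
average_replicates <- function(records, by = c("analyte_id", "soil_id")) {
  grouped <- dplyr::group_by(records, dplyr::across(dplyr::all_of(by)))
  dplyr::summarise(
    grouped,
    n_replicates = dplyr::n(),
    n_quantified = sum(.data$censor == "quantified"),
    conc_ng_g = if (any(.data$censor == "quantified")) {
      mean(.data$conc_ng_g[.data$censor == "quantified"])
    } else {
      NA_real_
    },
    censor = if (any(.data$censor == "quantified")) {
      "quantified"
    } else {
      names(sort(table(.data$censor), decreasing = TRUE))[1]
    },
    mloq_applied = .data$mloq_applied[1],
    .groups = "drop"
  )
}

#' Site-level detection summary
#'
#' Aggregates censored, replicate-averaged records of one site: the number
#' of distinct quantified analytes, the sum concentration (censored values
#' contribute 0 by default, or MLOQ/2 behind the `censored_value` switch),
#' and counts by pesticide class.
#'
#' @param records Replicate-averaged records of one site (see
#'   [average_replicates()]).
#' @param config A `method_config` (supplies pesticide classes).
#' @param censored_value `"zero"` (default) or `"half_mloq"`.
#' @return A list: `n_detected`, `sum_conc_ng_g`, `class_counts` (named
#'   integer vector over detected classes).
#' @export
summarize_site <- function(records, config,
                           censored_value = c("zero", "half_mloq")) {
  censored_value <- match.arg(censored_value)
  quantified <- records[records$censor == "quantified", ]
  contrib <- sum(quantified$conc_ng_g)
  if (censored_value == "half_mloq") {
    cens <- records[records$censor %in% c("below_mloq", "unconfirmed") &
                      !is.na(records$mloq_applied), ]
    contrib <- contrib + sum(cens$mloq_applied / 2)
  }
  classes <- config$analytes$pesticide_class[
    match(quantified$analyte_id, config$analytes$analyte_id)]
  list(
    n_detected = nrow(quantified),
    sum_conc_ng_g = contrib,
    class_counts = if (nrow(quantified) > 0) {
      table(classes)
    } else {
      table(character())
    }
  )
}

#' Signed percentage difference between two group results
#'
#' `100 * (x - y) / x`: the relative change of group `y` against group `x`,
#' signed, with `x` the reference in the denominator.
#'
#' @param x Reference group result (non-zero).
#' @param y Comparison group result.
#' @return Difference in percent; `NA` with a warning where `x == 0`.
#' @examples
#' percentage_difference(10, 8.7)
#' @export
percentage_difference <- function(x, y) {
  out <- 100 * (x - y) / x
  if (any(x == 0)) {
    warning("percentage_difference undefined where x == 0; returning NA.")
    out[x == 0] <- NA_real_
  }
  out
}

#' Compare two replicate groups (F-test then homoscedastic t-test)
#'
#' Group means are compared with a two-sided two-sample t-test assuming
#' equal variances; the equal-variance assumption is checked beforehand
#' with a two-sided F-test. Significance is declared at p < `alpha`.
#'
#' @param a,b Numeric vectors of replicate values (each n >= 2).
#' @param alpha Significance level (default 0.05).
#' @return A list: `f_p`, `t_p`, `t_statistic`, `significant`,
#'   `variances_equal` (F-test at the same alpha). Two groups with zero
#'   variance and equal means return `t_p = 1` by convention.
#' @examples
#' compare_groups(c(1, 2, 3), c(11, 12, 13))
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(f_p = 1, t_p = 1, t_statistic = 0, significant = FALSE,
                  variances_equal = TRUE))
    }
    return(list(f_p = 1, t_p = 0, t_statistic = Inf, significant = TRUE,
                variances_equal = TRUE))
  }
  f <- stats::var.test(a, b)
  t <- stats::t.test(a, b, var.equal = TRUE)
  list(
    f_p = unname(f$p.value),
    t_p = unname(t$p.value),
    t_statistic = unname(t$statistic),
    significant = t$p.value < alpha,
    variances_equal = f$p.value >= alpha
  )
}
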