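#' Electrospray matrix effect of an extract
#'
#' The matrix effect in percent is
#' `(1 - (pa_spiked - pa_unspiked) / pa_reference) * (-100)`:
#' the net analyte response in the matrix extract (post-extraction spike
#' minus native background) compared with a reference response. Positive
#' values indicate ion enhancement, negative values ion suppression. Two
#' reference cases are used: a standard prepared in pure solvent
#' (`solvent_standard`, case i) or the net response in the calibration
#' matrix extract (`s2_extract`, case ii); in case ii the calibration
#' matrix compared against itself gives exactly 0.
#'
#' @param pa_spiked Mean quantifier peak area of the post-extraction-spiked
#'   extracts.
#' @param pa_unspiked Mean quantifier peak area of the unspiked extracts.
#' @param pa_reference Mean reference peak area (> 0): the solvent standard
#'   (case i) or spiked-minus-unspiked calibration-matrix response
#'   (case ii).
#' @return Matrix effect in percent, vectorised.
#' @examples
#' matrix_effect(600, 100, 1000)   # -50: suppression
#' matrix_effect(1300, 100, 1000)  # +20: enhancement
#' @export
matrix_effect <- function(pa_spiked, pa_unspiked, pa_reference) {
  if (any(!is.finite(pa_reference)) || any(pa_reference <= 0)) {
    abort_soilmrm("pa_reference must be positive.", "soilmrm_domain_error")
  }
  (1 - (pa_spiked - pa_unspiked) / pa_reference) * (-100)
}

#' Matrix effects per analyte and soil from a batch
#'
#' Computes the matrix effect for every analyte in every soil of a
#' matrix-effect experiment: per soil, extracts spiked after extraction
#' (role `spike_post_extraction`) and unspiked extracts (role
#' `matrix_blank`), plus either solvent standards at the same level
#' (reference case `solvent_standard`) or the spiked-minus-unspiked
#' response of the calibration matrix (reference case `s2_extract`).
#' Peak areas are averaged over replicates before the ratio is formed.
#' Pairs where the spiked response does not exceed the unspiked one are
#' flagged (`input_flag`), not dropped.
#'
#' @param measurements,config,design Batch inputs.
#' @param reference_case `"solvent_standard"` (case i) or `"s2_extract"`
#'   (case ii).
#' @param cal_soil_id Calibration matrix used as case-ii reference.
#' @param solvent_soil_id Pseudo-soil of the solvent standards.
#' @return Tibble `analyte_id, soil_id, reference_case, pa_spiked,
#'   pa_unspiked, pa_reference, me_pct, input_flag`.
#' @export
compute_matrix_effects <- function(measurements, config, design,
                                   reference_case = c("solvent_standard",
                                                      "s2_extract"),
                                   cal_soil_id = "S2",
                                   solvent_soil_id = "SOLVENT") {
  reference_case <- match.arg(reference_case)

  mean_area <- function(sample_ids) {
    meas <- measurements[measurements$sample_id %in% sample_ids &
                           measurements$transition_role == "quantifier", ]
    map <- dplyr::bind_rows(lapply(config$analytes$analyte_id, function(a) {
      tibble::tibble(analyte_id = a, species_id = analyte_species(config, a))
    }))
    m <- dplyr::inner_join(meas, map, by = "species_id")
    per_sample <- dplyr::summarise(
      dplyr::group_by(m, .data$sample_id, .data$analyte_id),
      area = sum(.data$peak_area), .groups = "drop"
    )
    dplyr::summarise(
      dplyr::group_by(per_sample, .data$analyte_id),
      area = mean(.data$area), .groups = "drop"
    )
  }

  spiked_ids <- function(soil) {
    design$sample_id[design$role == "spike_post_extraction" &
                       design$soil_id == soil]
  }
  unspiked_ids <- function(soil) {
    design$sample_id[design$role == "matrix_blank" &
                       design$soil_id == soil]
  }

  soils <- setdiff(unique(design$soil_id[design$role ==
                                           "spike_post_extraction"]),
                   solvent_soil_id)
  if (reference_case == "s2_extract") {
    soils <- setdiff(soils, character(0))
    sp2 <- mean_area(spiked_ids(cal_soil_id))
    un2 <- mean_area(unspiked_ids(cal_soil_id))
    ref <- dplyr::left_join(sp2, un2, by = "analyte_id",
                            suffix = c("_sp", "_un"))
    ref$pa_reference <- ref$area_sp -
      ifelse(is.na(ref$area_un), 0, ref$area_un)
    ref <- ref[, c("analyte_id", "pa_reference")]
  } else {
    # the reference must be a solvent standard at the spike level itself,
    # not e.g. a co-acquired dilution series
    spike_level <- unique(stats::na.omit(
      design$nominal_level[design$role == "spike_post_extraction"]))
    if (length(spike_level) != 1L) {
      abort_soilmrm("Post-extraction spikes must share one nominal level.",
                    "soilmrm_config_error")
    }
    solvent <- design$sample_id[design$role == "cal_standard" &
                                  design$soil_id == solvent_soil_id &
                                  design$nominal_level == spike_level]
    if (length(solvent) == 0L) {
      abort_soilmrm(
        "No solvent standards at the spike level for reference case (i).",
        "soilmrm_config_error"
      )
    }
    ref <- mean_area(solvent)
    names(ref)[names(ref) == "area"] <- "pa_reference"
  }

  rows <- lapply(soils, function(soil) {
    sp <- mean_area(spiked_ids(soil))
    un <- mean_area(unspiked_ids(soil))
    df <- dplyr::left_join(sp, un, by = "analyte_id",
                           suffix = c("_sp", "_un"))
    df$area_un[is.na(df$area_un)] <- 0
    df <- dplyr::left_join(df, ref, by = "analyte_id")
    tibble::tibble(
      analyte_id = df$analyte_id,
      soil_id = soil,
      reference_case = reference_case,
      pa_spiked = df$area_sp,
      pa_unspiked = df$area_un,
      pa_reference = df$pa_reference,
      me_pct = matrix_effect(df$area_sp, df$area_un, df$pa_reference),
      input_flag = df$area_sp < df$area_un
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-soil matrix-effect summary
#'
#' @param effects Output of [compute_matrix_effects()].
#' @return One row per soil (and reference case): median, min, max matrix
#'   effect and the analyte count.
#' @export
summarize_matrix_effects <- function(effects) {
  dplyr::summarise(
    dplyr::group_by(effects, .data$soil_id, .data$reference_case),
    median_me_pct = stats::median(.data$me_pct),
    min_me_pct = min(.data$me_pct),
    max_me_pct = max(.data$me_pct),
    n_analytes = dplyr::n(),
    .groups = "drop"
  )
}

#' Derive the global matrix correction factor
#'
#' Method limits of quantification are determined in one calibration matrix
#' but applied to arbitrary soils, so they are inflated by a single global
#' factor covering the ion suppression other matrices may add relative to
#' the calibration matrix (reference case ii). The factor is derived from
#' the case-ii matrix-effect distribution: choose the smallest suppression
#' magnitude `s` from a candidate grid such that at most `max_exceedances`
#' analytes (counting each analyte's worst soil, the default) — or
#' analyte x soil pairs in `"pooled"` mode — show suppression stronger than
#' `-s`; the factor is `1 / (1 - s/100)`, rounded up to the configured
#' granularity. A maximal allowed suppression of -50% gives a factor of
#' exactly 2.
#'
#' @param effects Case-ii matrix effects (output of
#'   [compute_matrix_effects()] with `reference_case = "s2_extract"`), or
#'   any tibble with `analyte_id`, `soil_id`, `me_pct`.
#' @param max_exceedances Number of analytes (or pairs) allowed beyond the
#'   covered suppression (default 3).
#' @param candidate_suppressions Grid of suppression magnitudes in percent.
#' @param granularity Upward rounding granularity of the factor
#'   (default 0.5, conservative).
#' @param mode `"per_analyte"` (default; an analyte exceeds if its worst
#'   soil does) or `"pooled"` (each analyte x soil pair counts).
#' @return A list: `factor`, `suppression_pct` (the covered magnitude),
#'   `n_exceeded`, `exceeded_analytes` (flagged, not exempted), and
#'   `satisfied` (`FALSE` with a warning when no grid value meets the
#'   constraint and the largest is reported).
#' @examples
#' eff <- tibble::tibble(
#'   analyte_id = sprintf("A%02d", 1:6),
#'   soil_id = "S4",
#'   me_pct = c(-45, -30, -20, -10, -55, -60)
#' )
#' derive_global_factor(eff, max_exceedances = 2)
#' @export
derive_global_factor <- function(effects, max_exceedances = 3,
                                 candidate_suppressions = seq(0, 95, by = 5),
                                 granularity = 0.5,
                                 mode = c("per_analyte", "pooled")) {
  mode <- match.arg(mode)
  assert_number(max_exceedances, "max_exceedances", lower = 0)
  if (any(candidate_suppressions < 0 | candidate_suppressions >= 100)) {
    abort_soilmrm("candidate_suppressions must be in [0, 100).",
                  "soilmrm_domain_error")
  }
  worst <- if (mode == "per_analyte") {
    dplyr::summarise(dplyr::group_by(effects, .data$analyte_id),
                     me_pct = min(.data$me_pct), .groups = "drop")
  } else {
    effects
  }
  grid <- sort(candidate_suppressions)
  counts <- vapply(grid, function(s) sum(worst$me_pct < -s), 0L)
  ok <- which(counts <= max_exceedances)
  satisfied <- length(ok) > 0L
  if (!satisfied) {
    warning("No candidate suppression satisfies the exceedance constraint; ",
            "reporting the largest grid value.")
    s <- max(grid)
  } else {
    s <- grid[ok[1]]
  }
  raw <- 1 / (1 - s / 100)
  # upward rounding to the granularity grid; the epsilon keeps a factor
  # already on the grid (e.g. exactly 2) from being bumped a notch
  factor <- ceiling(raw / granularity - 1e-9) * granularity
  exceeded <- worst$analyte_id[worst$me_pct < -s]
  list(
    factor = factor,
    suppression_pct = s,
    n_exceeded = length(exceeded),
    exceeded_analytes = exceeded,
    satisfied = satisfied
  )
}
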