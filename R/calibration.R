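#' Peak-area ratios for a set of samples
#'
#' The calibration response variable is the peak-area ratio (PAR): the
#' analyte quantifier area — summed over stereoisomer peaks where these are
#' integrated separately — divided by the quantifier area of the analyte's
#' assigned ILIS. A zero ILIS area makes the PAR undefined; such rows are
#' flagged (`par_defined = FALSE`) rather than raising an error, and the
#' affected sample is excluded from fits and quantification.
#'
#' @param measurements A validated measurement tibble.
#' @param config A `method_config` with ILIS assignments resolved for every
#'   analyte of interest.
#' @param analyte_ids Analytes to compute (default: all with an assigned
#'   ILIS).
#' @param ilis_override Optional named character vector `analyte_id ->
#'   ilis_id` that overrides the configured assignment (used during ILIS
#'   candidate screening).
#' @return Tibble `sample_id, analyte_id, ilis_id, analyte_area, ilis_area,
#'   par, par_defined`.
#' @export
compute_par <- function(measurements, config, analyte_ids = NULL,
                        ilis_override = NULL) {
  an <- config$analytes
  if (is.null(analyte_ids)) {
    analyte_ids <- an$analyte_id[!is.na(an$assigned_ilis_id) |
                                   an$analyte_id %in% names(ilis_override)]
  }
  ilis_for <- an$assigned_ilis_id[match(analyte_ids, an$analyte_id)]
  if (!is.null(ilis_override)) {
    hit <- match(analyte_ids, names(ilis_override))
    ilis_for[!is.na(hit)] <- unname(ilis_override[hit[!is.na(hit)]])
  }
  if (anyNA(ilis_for)) {
    abort_soilmrm(
      sprintf("No ILIS assigned for analyte(s): %s",
              paste(analyte_ids[is.na(ilis_for)], collapse = ", ")),
      "soilmrm_reference_error"
    )
  }

  quant <- measurements[measurements$transition_role == "quantifier", ]
  # analyte quantifier area, stereoisomer peaks summed
  st <- config$stereoisomers
  species_map <- tibble::tibble(analyte_id = analyte_ids)
  species_map <- dplyr::rowwise(species_map)
  species_map <- dplyr::mutate(
    species_map,
    species = list(analyte_species(config, .data$analyte_id))
  )
  species_map <- tidyr::unnest(dplyr::ungroup(species_map), "species")

  an_area <- dplyr::inner_join(quant, species_map,
                               by = c(species_id = "species"))
  an_area <- dplyr::summarise(
    dplyr::group_by(an_area, .data$sample_id, .data$analyte_id),
    analyte_area = sum(.data$peak_area),
    .groups = "drop"
  )
  il_area <- quant[quant$species_id %in% unique(ilis_for),
                   c("sample_id", "species_id", "peak_area")]
  names(il_area) <- c("sample_id", "ilis_id", "ilis_area")

  out <- dplyr::mutate(an_area,
                       ilis_id = ilis_for[match(.data$analyte_id, analyte_ids)])
  out <- dplyr::left_join(out, il_area, by = c("sample_id", "ilis_id"))
  out$ilis_area[is.na(out$ilis_area)] <- 0
  out$par_defined <- out$ilis_area > 0
  out$par <- ifelse(out$par_defined, out$analyte_area / out$ilis_area,
                    NA_real_)
  out[, c("sample_id", "analyte_id", "ilis_id", "analyte_area", "ilis_area",
          "par", "par_defined")]
}

#' Fit a 1/x-weighted linear calibration curve
#'
#' Matrix-matched internal-standard calibration: the PAR of each
#' calibration standard is regressed on its nominal concentration by
#' linear least squares with weights `1/x`, which equalises the relative
#' influence of levels across the two to three decades a residue
#' calibration spans. Replicate standards at a level enter as individual
#' points. The intercept is estimated, not forced through zero.
#'
#' @param conc Nominal concentrations (ng/mL), all positive.
#' @param par Peak-area ratios, same length.
#' @param weighting `"one_over_x"` (the default and only weighting the
#'   method uses) or `"none"`.
#' @param min_levels Minimum number of distinct usable levels (default 5).
#' @return An object of class `calibration_curve`: slope, intercept,
#'   weighted and unweighted R², per-level back-calculation table
#'   (`nominal`, `backcalc`, `deviation_pct`), and bookkeeping fields.
#' @examples
#' x <- c(0.05, 0.1, 0.25, 0.5, 1, 2.5, 5, 10, 17.5, 25, 35, 50)
#' fit_calibration(x, 0.1 * x)
#' @export
fit_calibration <- function(conc, par, weighting = c("one_over_x", "none"),
                            min_levels = 5) {
  weighting <- match.arg(weighting)
  keep <- is.finite(conc) & is.finite(par)
  conc <- conc[keep]
  par <- par[keep]
  if (any(conc <= 0)) {
    abort_soilmrm("Nominal levels must be positive for 1/x weighting.",
                  "soilmrm_domain_error")
  }
  if (length(unique(conc)) < min_levels) {
    abort_soilmrm(
      sprintf("Calibration needs >= %d distinct levels with defined PAR (got %d).",
              min_levels, length(unique(conc))),
      "soilmrm_insufficient_calibration_error"
    )
  }
  w <- if (weighting == "one_over_x") 1 / conc else rep(1, length(conc))
  fit <- stats::lm(par ~ conc, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])

  # weighted R^2 on the weighted residuals (consistent with the fit);
  # the unweighted one is kept alongside
  r2_w <- wls_core(conc, par, w)$r_squared
  r2_u <- wls_core(conc, par, rep(1, length(conc)))$r_squared

  backcalc_pt <- (par - intercept) / slope
  levels <- sort(unique(conc))
  level_backcalc <- tibble::tibble(
    nominal = levels,
    par_mean = vapply(levels, function(l) mean(par[conc == l]), 0),
    backcalc = vapply(levels, function(l) mean(backcalc_pt[conc == l]), 0)
  )
  level_backcalc$deviation_pct <-
    100 * (level_backcalc$backcalc - level_backcalc$nominal) /
    level_backcalc$nominal

  structure(
    list(
      slope = slope,
      intercept = intercept,
      r_squared = r2_w,
      r_squared_unweighted = r2_u,
      weighting = weighting,
      n_points = length(conc),
      n_levels_used = length(levels),
      level_backcalc = level_backcalc,
      linear_low = min(levels),
      linear_high = max(levels)
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve>\n")
  cat(sprintf("  PAR = %.6g + %.6g * conc  (weighting: %s)\n",
              x$intercept, x$slope, x$weighting))
  cat(sprintf("  R2 (weighted): %.6f, levels: %d, points: %d\n",
              x$r_squared, x$n_levels_used, x$n_points))
  cat(sprintf("  linear range: %.3g-%.3g ng/mL\n",
              x$linear_low, x$linear_high))
  invisible(x)
}

#' Review calibration linearity and trim the linear range
#'
#' A calibration level passes linearity review if its back-calculated
#' concentration deviates from nominal by at most `tol_pct` percent
#' (boundary inclusive). Failing levels are removed only from the edges of
#' the level series (contiguous trimming, so a single linear range
#' remains); interior failures are flagged for manual review but do not
#' truncate the range. The lower edge can additionally be constrained by a
#' per-level qualification flag (signal-to-noise and ion-ratio rules, see
#' [determine_mloq()]) through `level_ok`.
#'
#' @param curve A `calibration_curve`.
#' @param tol_pct Allowed deviation in percent (default 20).
#' @param level_ok Optional logical vector along the curve's levels; levels
#'   with `FALSE` cannot form the lower edge of the linear range.
#' @return A list: `levels` (per-level tibble with `pass`, `trimmed`,
#'   `interior_flag`), `linear_low`, `linear_high`, `n_interior_failures`.
#' @export
review_linearity <- function(curve, tol_pct = 20, level_ok = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  lb <- curve$level_backcalc
  n <- nrow(lb)
  pass <- abs(lb$deviation_pct) <= tol_pct
  ok <- if (is.null(level_ok)) rep(TRUE, n) else as.logical(level_ok)
  stopifnot(length(ok) == n)

  usable <- pass & ok
  lo <- which(usable)[1]
  if (is.na(lo)) {
    abort_soilmrm("No calibration level passes linearity review.",
                  "soilmrm_no_linear_range_error")
  }
  hi <- n
  while (hi > lo && !pass[hi]) hi <- hi - 1
  trimmed <- seq_len(n) < lo | seq_len(n) > hi
  interior <- !pass & !trimmed

  list(
    levels = tibble::tibble(
      nominal = lb$nominal,
      backcalc = lb$backcalc,
      deviation_pct = lb$deviation_pct,
      pass = pass,
      qualified = ok,
      trimmed = trimmed,
      interior_flag = interior
    ),
    linear_low = lb$nominal[lo],
    linear_high = lb$nominal[hi],
    n_interior_failures = sum(interior)
  )
}

#' Calibrate every analyte of a batch
#'
#' Extracts the matrix-matched calibration standards of a batch, computes
#' PARs, fits the 1/x-weighted curve per analyte, reviews linearity with
#' contiguous edge trimming, refits on the trimmed level set, and returns
#' one row per analyte. Analytes whose ILIS area is zero in some standards
#' lose those points (flagged); analytes with fewer than `min_levels`
#' usable levels are reported with `fitted = FALSE`.
#'
#' @param measurements,config,design Batch inputs.
#' @param cal_soil_id Soil of the matrix-matched standards (default
#'   `"S2"`).
#' @param tol_pct Linearity tolerance in percent (default: the configured
#'   `linearity_tol_pct`).
#' @param level_ok Optional tibble `analyte_id, nominal, ok` of per-level
#'   qualification flags constraining the lower range edge.
#' @param ilis_override Passed to [compute_par()].
#' @param min_levels Minimum distinct levels per fit.
#' @return A tibble of class `calibration_table`: `analyte_id, ilis_id,
#'   slope, intercept, r_squared, r_squared_unweighted, linear_low,
#'   linear_high, n_levels_used, n_interior_failures, fitted`, with the
#'   fitted `calibration_curve` objects in the list-column `curve`.
#' @export
calibrate_batch <- function(measurements, config, design,
                            cal_soil_id = "S2", tol_pct = NULL,
                            level_ok = NULL, ilis_override = NULL,
                            min_levels = 5) {
  tol_pct <- tol_pct %||% config$params$linearity_tol_pct
  cal <- design[design$role == "cal_standard" &
                  design$soil_id == cal_soil_id, ]
  if (nrow(cal) == 0L) {
    abort_soilmrm(sprintf("No calibration standards in soil %s.", cal_soil_id),
                  "soilmrm_insufficient_calibration_error")
  }
  meas_cal <- measurements[measurements$sample_id %in% cal$sample_id, ]
  pars <- compute_par(meas_cal, config, ilis_override = ilis_override)
  pars$nominal <- cal$nominal_level[match(pars$sample_id, cal$sample_id)]

  rows <- lapply(split(pars, pars$analyte_id), function(df) {
    aid <- df$analyte_id[1]
    usable <- df[df$par_defined, ]
    base <- tibble::tibble(
      analyte_id = aid, ilis_id = df$ilis_id[1],
      slope = NA_real_, intercept = NA_real_,
      r_squared = NA_real_, r_squared_unweighted = NA_real_,
      linear_low = NA_real_, linear_high = NA_real_,
      n_levels_used = 0L, n_interior_failures = 0L,
      n_undefined_par = sum(!df$par_defined),
      fitted = FALSE, curve = list(NULL)
    )
    if (length(unique(usable$nominal)) < min_levels) {
      return(base)
    }
    fit0 <- fit_calibration(usable$nominal, usable$par,
                            min_levels = min_levels)
    ok <- NULL
    if (!is.null(level_ok)) {
      sub <- level_ok[level_ok$analyte_id == aid, ]
      ok <- sub$ok[match(fit0$level_backcalc$nominal, sub$nominal)]
      ok[is.na(ok)] <- TRUE
    }
    rev0 <- review_linearity(fit0, tol_pct, level_ok = ok)
    keep <- usable$nominal >= rev0$linear_low &
      usable$nominal <= rev0$linear_high
    fit <- if (any(rev0$levels$trimmed)) {
      if (length(unique(usable$nominal[keep])) < min_levels) {
        fit0
      } else {
        fit_calibration(usable$nominal[keep], usable$par[keep],
                        min_levels = min_levels)
      }
    } else {
      fit0
    }
    fit$linear_low <- rev0$linear_low
    fit$linear_high <- rev0$linear_high
    base$slope <- fit$slope
    base$intercept <- fit$intercept
    base$r_squared <- fit$r_squared
    base$r_squared_unweighted <- fit$r_squared_unweighted
    base$linear_low <- rev0$linear_low
    base$linear_high <- rev0$linear_high
    base$n_levels_used <- fit$n_levels_used
    base$n_interior_failures <- rev0$n_interior_failures
    base$fitted <- TRUE
    base$curve <- list(fit)
    base
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("calibration_table", class(out))
  out
}
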