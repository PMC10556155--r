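#' Define a simulation scenario
#'
#' A scenario fixes the data-generating mechanism for synthetic MRM
#' batches: soil-dependent electrospray matrix effects whose systematic
#' part scales with organic carbon and whose analyte-specific part is
#' correlated across species through retention time, extraction losses
#' shared between each analyte and a pre-extraction-spiked ILIS according
#' to the same retention-time kernel, multiplicative lognormal area noise,
#' and a per-species noise floor that defines signal-to-noise.
#'
#' The matrix effect injected for species `i` in the extract of soil `s` is
#' `ME(i, s) = suppression_slope * c_org(s) + suppression_sd * G_s(rt_i)`
#' (percent), where `G_s` is a standard stationary Gaussian field over
#' retention time with `cor(G(rt1), G(rt2)) = exp(-|rt1 - rt2| /
#' rt_corr_scale)`, drawn independently per soil extract. The pseudo-soil
#' `SOLVENT` (zero organic carbon) has exactly zero matrix effect. A
#' structure-identical ILIS receives its analyte's matrix effect and
#' extraction shock exactly (correlation 1); any other ILIS is correlated
#' with the analyte only through retention-time proximity — this is what
#' makes surrogate-ILIS selection by retention time meaningful.
#'
#' @param soils A `soil_table` defining the available matrices.
#' @param suppression_slope Matrix-effect change per percent organic
#'   carbon (default -8 %% per %% C_org: suppression grows with matrix
#'   complexity).
#' @param suppression_sd Species-specific matrix-effect dispersion
#'   (percentage points) around the organic-carbon trend.
#' @param rt_corr_scale Retention-time correlation scale (minutes) of both
#'   the matrix-effect and the extraction-shock fields.
#' @param extraction_recovery_mean,extraction_recovery_sd Mean extraction
#'   recovery (fraction) and the standard deviation of the per-sample,
#'   per-species recovery shock.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   peak-area noise (0.03 = 3%%); 0 gives a noise-free batch.
#' @param noise_floor_rel Per-species chromatographic noise floor expressed
#'   relative to the species response slope; signal-to-noise is
#'   `area / noise_floor`. The default 0.002 puts the quantifier S/N = 10
#'   point near 0.02 ng/mL for a typical analyte, emulating instrumental
#'   limits of quantification around 0.025 ng/mL and matrix-matched base
#'   limits at the lowest calibration levels.
#' @param qualifier_fraction_mean,qualifier_fraction_sd Distribution of the
#'   qualifier-to-quantifier response ratio per analyte (clipped to
#'   0.05--0.95).
#' @param response_slope_meanlog,response_slope_sdlog Lognormal parameters
#'   of the per-species detector response (area per ng/mL).
#' @param rt_jitter_sd_min Standard deviation (minutes) of observed
#'   retention times around the expected ones.
#' @param seed Integer master seed. Every random draw is keyed to this seed
#'   plus a stream label (species id, soil id or sample id), so a fixed
#'   seed reproduces a batch bit for bit and draws attached to one
#'   identifier do not move when unrelated identifiers are added.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(soils = default_soils(),
                         suppression_slope = -8,
                         suppression_sd = 10,
                         rt_corr_scale = 1.0,
                         extraction_recovery_mean = 0.95,
                         extraction_recovery_sd = 0.05,
                         noise_cv = 0.03,
                         noise_floor_rel = 0.002,
                         qualifier_fraction_mean = 0.4,
                         qualifier_fraction_sd = 0.15,
                         response_slope_meanlog = log(2000),
                         response_slope_sdlog = 0.6,
                         rt_jitter_sd_min = 0.01,
                         seed = 1) {
  assert_number(noise_cv, "noise_cv", lower = 0)
  assert_number(extraction_recovery_sd, "extraction_recovery_sd", lower = 0)
  assert_number(suppression_sd, "suppression_sd", lower = 0)
  assert_number(rt_corr_scale, "rt_corr_scale",
                lower = .Machine$double.eps)
  assert_number(qualifier_fraction_mean, "qualifier_fraction_mean",
                lower = 0, upper = 1)
  assert_number(rt_jitter_sd_min, "rt_jitter_sd_min", lower = 0)
  assert_number(noise_floor_rel, "noise_floor_rel", lower = 0)
  structure(
    list(
      soils = soils,
      suppression_slope = suppression_slope,
      suppression_sd = suppression_sd,
      rt_corr_scale = rt_corr_scale,
      extraction_recovery_mean = extraction_recovery_mean,
      extraction_recovery_sd = extraction_recovery_sd,
      noise_cv = noise_cv,
      noise_floor_rel = noise_floor_rel,
      qualifier_fraction_mean = qualifier_fraction_mean,
      qualifier_fraction_sd = qualifier_fraction_sd,
      response_slope_meanlog = response_slope_meanlog,
      response_slope_sdlog = response_slope_sdlog,
      rt_jitter_sd_min = rt_jitter_sd_min,
      seed = as.integer(seed)
    ),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario>\n")
  cat(sprintf("  soils: %s\n", paste(x$soils$soil_id, collapse = ", ")))
  cat(sprintf("  suppression: %+.3g%%/%%C_org (sd %.3g, RT scale %.3g min)\n",
              x$suppression_slope, x$suppression_sd, x$rt_corr_scale))
  cat(sprintf("  extraction recovery: %.3g (sd %.3g)\n",
              x$extraction_recovery_mean, x$extraction_recovery_sd))
  cat(sprintf("  area noise CV: %.3g, seed: %d\n", x$noise_cv, x$seed))
  invisible(x)
}

# --- retention-time-correlated Gaussian fields ------------------------------
#
# Fields are realised on a fixed 0.1-min grid as a stationary AR(1)
# (Ornstein-Uhlenbeck) process with lag-one correlation exp(-0.1/scale), so
# any two grid points k steps apart have correlation exp(-0.1 k / scale) =
# exp(-|delta RT| / scale). Species read the field at the nearest grid
# point. The grid is fixed (0..30 min) and each field is keyed by its
# stream label, so the realisation for one soil or sample never depends on
# which species look at it.

rt_field_grid <- seq(0, 30, by = 0.1)

rt_field <- function(seed_key, scale) {
  n <- length(rt_field_grid)
  z <- with_seed(seed_key, stats::rnorm(n))
  rho <- exp(-0.1 / scale)
  x <- as.numeric(stats::filter(c(z[1], z[-1] * sqrt(1 - rho^2)), rho,
                                method = "recursive"))
  x
}

field_at <- function(field, rt) {
  idx <- pmin(pmax(round(rt / 0.1) + 1L, 1L), length(rt_field_grid))
  field[idx]
}

# Species-level truth table shared by all batches generated under one
# (config, scenario) pair: detector response, qualifier fraction, noise
# floor, stereoisomer area split.
species_truth <- function(config, scenario) {
  st <- config$stereoisomers
  members <- st$species_id %||% character()
  sp_ids <- measured_species(config)
  tr_q <- config$transitions[config$transitions$role == "quantifier", ]
  rt <- tr_q$expected_rt[match(sp_ids, tr_q$species_id)]
  parent <- ifelse(sp_ids %in% members,
                   st$analyte_id[match(sp_ids, st$species_id)], sp_ids)
  kind <- ifelse(parent %in% config$ilis$ilis_id, "ilis", "analyte")

  draws <- vapply(sp_ids, function(sid) {
    with_seed(hash_seed(scenario$seed, "species", sid), {
      c(
        slope = stats::rlnorm(1, scenario$response_slope_meanlog,
                              scenario$response_slope_sdlog),
        qualfrac = min(max(stats::rnorm(1, scenario$qualifier_fraction_mean,
                                        scenario$qualifier_fraction_sd),
                           0.05), 0.95),
        floorfac = stats::rlnorm(1, 0, 0.5)
      )
    })
  }, c(slope = 0, qualfrac = 0, floorfac = 0))

  floorfac <- unname(draws["floorfac", ])
  out <- tibble::tibble(
    species_id = sp_ids,
    parent_id = unname(parent),
    kind = unname(kind),
    expected_rt = unname(rt),
    response_slope = unname(draws["slope", ]),
    qualifier_fraction = unname(draws["qualfrac", ]),
    noise_floor_area = unname(draws["slope", ]) * scenario$noise_floor_rel *
      floorfac,
    isomer_fraction = 1
  )
  # stereoisomer members share the parent compound's response and split
  # its amount with a fixed fraction
  if (length(members) > 0L) {
    for (p in unique(st$analyte_id)) {
      ids <- st$species_id[st$analyte_id == p]
      fr <- with_seed(hash_seed(scenario$seed, "isomer", p),
                      stats::runif(length(ids), 0.3, 0.7))
      fr <- fr / sum(fr)
      i <- match(ids, out$species_id)
      parent_slope <- with_seed(hash_seed(scenario$seed, "species", p),
                                stats::rlnorm(1, scenario$response_slope_meanlog,
                                              scenario$response_slope_sdlog))
      out$response_slope[i] <- parent_slope
      out$noise_floor_area[i] <- parent_slope * scenario$noise_floor_rel *
        floorfac[i]
      out$isomer_fraction[i] <- fr
    }
  }
  out
}

# Matrix effect (%) per soil x species; structure-identical ILIS copy
# their analyte's value exactly, SOLVENT is exactly zero.
matrix_effect_truth <- function(config, scenario, species) {
  soils <- scenario$soils
  rows <- lapply(seq_len(nrow(soils)), function(i) {
    soil <- soils$soil_id[i]
    c_org <- soils$c_org_pct[i]
    if (c_org == 0) {
      me <- rep(0, nrow(species))
    } else {
      g <- rt_field(hash_seed(scenario$seed, "me", soil),
                    scenario$rt_corr_scale)
      me <- scenario$suppression_slope * c_org +
        scenario$suppression_sd * field_at(g, species$expected_rt)
      si <- match(config$analytes$si_ilis_id, species$species_id)
      src <- match(config$analytes$analyte_id, species$species_id)
      ok <- !is.na(si) & !is.na(src)
      me[si[ok]] <- me[src[ok]]
      me <- pmin(pmax(me, -95), 400)
    }
    tibble::tibble(soil_id = soil, species_id = species$species_id,
                   me_pct = me)
  })
  dplyr::bind_rows(rows)
}

#' Generate a synthetic MRM batch with known ground truth
#'
#' Produces a long-format measurement table (one row per sample x
#' transition, with peak area, signal-to-noise and observed retention time)
#' for an arbitrary batch design, together with a `sim_truth` object
#' holding everything needed to compute expected outcomes in closed form:
#' per-species response slopes, qualifier fractions and noise floors,
#' per-soil matrix effects, per-sample extraction recoveries and the native
#' concentrations used.
#'
#' The quantifier area of species `i` in sample `j` is
#' `extract_conc * response_slope * (1 + ME/100)` times multiplicative
#' lognormal noise with total CV `noise_cv`, split evenly (in variance)
#' between a per-injection common-mode factor shared by all species of the
#' sample and a species-specific residual — so a peak-area ratio retains a
#' CV of about `noise_cv` while the common-mode part cancels, as it does
#' for a real internal standard. The qualifier area is the realised
#' quantifier area times the species' qualifier fraction times an
#' independent lognormal factor with CV `noise_cv`, and S/N is area
#' divided by the species' noise floor. Extract concentrations follow
#' the sample role: calibration standards and post-extraction spikes are
#' volumetric additions unaffected by extraction recovery; native residues
#' and pre-extraction spikes pass through the soil-mass/extract-volume
#' ratio and the per-sample recovery; the ILIS MIX contributes its tier
#' concentration scaled by the spike volume, with recovery applied only
#' when it was spiked before extraction.
#'
#' @param scenario A `sim_scenario`.
#' @param design A batch-design tibble (see [design_builders]).
#' @param config A `method_config`.
#' @param native_conc Optional tibble `analyte_id, soil_id, conc_ng_g` of
#'   native residue concentrations (dry weight); missing pairs are 0.
#' @return A list of class `sim_batch` with elements `measurements`
#'   (validated measurement tibble), `truth` (a `sim_truth`) and `design`.
#' @export
simulate_batch <- function(scenario, design, config, native_conc = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"),
            inherits(config, "method_config"))
  validate_batch_design(design, scenario$soils)
  if (any(design$ilis_pre_extraction) &&
      config$params$ilis_spike_volume_uL <= 0) {
    abort_soilmrm(
      "Design requests a pre-extraction ILIS spike but ilis_spike_volume_uL is zero.",
      "soilmrm_design_error"
    )
  }

  species <- species_truth(config, scenario)
  me_tbl <- matrix_effect_truth(config, scenario, species)
  soils <- scenario$soils

  n_sp <- nrow(species)
  is_ilis <- species$kind == "ilis"
  ilis_tier <- config$ilis$tier_concentration[
    match(species$parent_id, config$ilis$ilis_id)]
  # si_src[i]: index of the analyte species whose matrix effect and
  # extraction shock a structure-identical ILIS copies (first stereoisomer
  # member when the analyte is measured through member peaks)
  si_of_ilis <- config$analytes$analyte_id[
    match(species$parent_id, config$analytes$si_ilis_id)]
  si_src <- match(si_of_ilis, species$parent_id)

  if (is.null(native_conc)) {
    native_conc <- tibble::tibble(analyte_id = character(),
                                  soil_id = character(),
                                  conc_ng_g = numeric())
  }

  spike_uL <- config$params$ilis_spike_volume_uL
  rows <- vector("list", nrow(design))
  recovery_rows <- vector("list", nrow(design))

  for (j in seq_len(nrow(design))) {
    smp <- design[j, ]
    soil_i <- match(smp$soil_id, soils$soil_id)
    water <- soils$water_content_pct[soil_i]
    dm <- dry_weight_equivalent(smp$soil_mass_g, water)
    me <- me_tbl$me_pct[me_tbl$soil_id == smp$soil_id][
      match(species$species_id,
            me_tbl$species_id[me_tbl$soil_id == smp$soil_id])]

    # per-sample extraction shock field, shared across species by RT
    if (scenario$extraction_recovery_sd > 0) {
      g <- rt_field(hash_seed(scenario$seed, "recovery", smp$sample_id),
                    scenario$rt_corr_scale)
      shock <- scenario$extraction_recovery_sd *
        field_at(g, species$expected_rt)
    } else {
      shock <- rep(0, n_sp)
    }
    recovery <- pmin(pmax(scenario$extraction_recovery_mean + shock,
                          0.05), 1.5)
    ok <- !is.na(si_src)
    recovery[ok] <- recovery[si_src[ok]]
    me[ok] <- me[si_src[ok]]

    # native + pre-extraction spike content, in ng/g dry weight
    nat <- native_conc$conc_ng_g[
      match(paste(species$parent_id, smp$soil_id),
            paste(native_conc$analyte_id, native_conc$soil_id))]
    nat[is.na(nat)] <- 0
    pre_ng_g <- nat
    if (smp$role %in% c("spike_pre_extraction")) {
      pre_ng_g <- pre_ng_g + ifelse(is_ilis, 0, smp$nominal_level)
    }
    pre_part <- if (dm > 0) {
      pre_ng_g * dm * recovery / smp$extract_volume_mL
    } else {
      rep(0, n_sp)
    }

    # volumetric additions into the extract, in ng/mL
    post_part <- rep(0, n_sp)
    if (smp$role %in% c("cal_standard", "spike_post_extraction")) {
      post_part <- ifelse(is_ilis, 0, smp$nominal_level)
    }
    extract_conc <- (pre_part + post_part) * species$isomer_fraction
    ilis_conc <- ilis_tier * (spike_uL / 1000) / smp$extract_volume_mL
    ilis_conc[is.na(ilis_conc)] <- 0
    if (smp$ilis_pre_extraction) {
      ilis_conc <- ilis_conc * recovery
    }
    extract_conc[is_ilis] <- ilis_conc[is_ilis]

    # area noise splits into a common-mode per-injection factor (shared by
    # every species in the sample, cancelled by the PAR) and a
    # species-specific residual; each carries cv/sqrt(2) so a single area
    # has CV = noise_cv while a peak-area ratio has CV ~ noise_cv as well
    noise <- with_seed(hash_seed(scenario$seed, "noise", smp$sample_id), {
      list(
        common = lognormal_factor(1, scenario$noise_cv / sqrt(2)),
        quant = lognormal_factor(n_sp, scenario$noise_cv / sqrt(2)),
        qual = lognormal_factor(n_sp, scenario$noise_cv),
        rt = if (scenario$rt_jitter_sd_min > 0) {
          stats::rnorm(2 * n_sp, 0, scenario$rt_jitter_sd_min)
        } else {
          rep(0, 2 * n_sp)
        }
      )
    })

    quant_area <- extract_conc * species$response_slope * (1 + me / 100) *
      noise$common * noise$quant
    qual_area <- quant_area * species$qualifier_fraction * noise$qual

    rows[[j]] <- tibble::tibble(
      sample_id = smp$sample_id,
      species_id = rep(species$species_id, 2),
      transition_role = rep(c("quantifier", "qualifier"), each = n_sp),
      peak_area = c(quant_area, qual_area),
      snr = c(quant_area, qual_area) / rep(species$noise_floor_area, 2),
      rt = rep(species$expected_rt, 2) + noise$rt
    )
    recovery_rows[[j]] <- tibble::tibble(
      sample_id = smp$sample_id,
      species_id = species$species_id,
      recovery = recovery
    )
  }

  measurements <- dplyr::bind_rows(rows)
  truth <- structure(
    list(
      species = species,
      matrix_effects = me_tbl,
      recovery = dplyr::bind_rows(recovery_rows),
      native_conc = native_conc,
      scenario = scenario
    ),
    class = "sim_truth"
  )
  structure(
    list(
      measurements = validate_measurements(measurements, config, design),
      truth = truth,
      design = design
    ),
    class = "sim_batch"
  )
}

#' @export
print.sim_batch <- function(x, ...) {
  cat("<sim_batch>\n")
  cat(sprintf("  samples: %d, measurement rows: %d\n",
              nrow(x$design), nrow(x$measurements)))
  invisible(x)
}

#' Construct an aged spiked reference soil
#'
#' An aged reference soil is prepared by spiking a blank matrix with every
#' target analyte at a common level and letting it equilibrate, so part of
#' each analyte becomes non-extractable or degrades before analysis. The
#' generator represents aging as a per-analyte loss fraction applied to the
#' spiked concentration: the remaining (extractable) truth is
#' `spike_ng_g * (1 - aging_loss)`.
#'
#' @param config A `method_config` (supplies the analyte list).
#' @param spike_ng_g Spiked concentration in ng/g dry weight (default 10).
#' @param aging_loss Either a single loss fraction in `[0, 1]` applied to
#'   all analytes or a named vector keyed by `analyte_id` (unnamed analytes
#'   get 0).
#' @param soil_id,c_org_pct,ph Identity and properties of the aged soil
#'   (defaults: the calibration matrix re-labelled `S2.1`).
#' @param n_replicates,day_ids,operator_ids Passed to
#'   [design_reference_aged()].
#' @return A list with `design`, `native_conc` (the post-aging truth, to be
#'   passed to [simulate_batch()]), and `soil` (a `soil_table` row to append
#'   to the scenario's soils).
#' @export
make_reference_aged <- function(config, spike_ng_g = 10, aging_loss = 0,
                                soil_id = "S2.1", c_org_pct = 2.0, ph = 7.4,
                                n_replicates = 2,
                                day_ids = c("d1", "d2", "d3"),
                                operator_ids = "op1") {
  assert_number(spike_ng_g, "spike_ng_g", lower = .Machine$double.eps)
  ids <- config$analytes$analyte_id
  if (is.null(names(aging_loss))) {
    loss <- rep_len(as.numeric(aging_loss), length(ids))
  } else {
    loss <- rep(0, length(ids))
    hit <- match(names(aging_loss), ids)
    if (anyNA(hit)) {
      abort_soilmrm("aging_loss names must be analyte ids.",
                    "soilmrm_reference_error")
    }
    loss[hit] <- as.numeric(aging_loss)
  }
  if (any(loss < 0 | loss > 1)) {
    abort_soilmrm("aging_loss fractions must be in [0, 1].",
                  "soilmrm_domain_error")
  }
  list(
    design = design_reference_aged(soil_id = soil_id,
                                   n_replicates = n_replicates,
                                   day_ids = day_ids,
                                   operator_ids = operator_ids),
    native_conc = tibble::tibble(
      analyte_id = ids,
      soil_id = soil_id,
      conc_ng_g = spike_ng_g * (1 - loss)
    ),
    soil = soil_table(soil_id, c_org_pct, ph)
  )
}
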