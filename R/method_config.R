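#' Assemble and validate a method configuration
#'
#' A method configuration bundles the analyte and internal-standard (ILIS)
#' catalogs, the MRM transition list, the calibration design and the
#' method-level quality parameters of a targeted LC-MS/MS multi-residue
#' method. All downstream stages (simulation, calibration, identification,
#' quantification, limits of quantification, ILIS assignment) consume this
#' object.
#'
#' @param analytes Tibble with columns `analyte_id`, `name`,
#'   `pesticide_class`, `polarity` (`"positive"`/`"negative"`), `expected_rt`
#'   (minutes) and optionally `stereoisomer_group`, `si_ilis_id`,
#'   `assigned_ilis_id`. An analyte with a structure-identical ILIS
#'   (`si_ilis_id`) is always quantified against it; `assigned_ilis_id` is
#'   filled for the remaining analytes by [assign_ilis()].
#' @param ilis Tibble with columns `ilis_id`, `name`, `polarity`,
#'   `expected_rt`, `tier_concentration` (ng/mL in the ILIS MIX solution;
#'   must be one of `ilis_tiers`).
#' @param transitions Tibble with columns `species_id`, `role`
#'   (`"quantifier"`/`"qualifier"`), `precursor_mz`, `product_mz`,
#'   `polarity`, `expected_rt`. Every measured species (analyte, stereoisomer
#'   peak, or ILIS) carries exactly one quantifier and one qualifier.
#' @param stereoisomers Optional tibble `species_id`, `analyte_id` mapping
#'   chromatographically separated stereoisomer peaks to their analyte; the
#'   peak areas of all members are summed before quantification. Analytes
#'   listed here are measured only through their member species.
#' @param cal_levels Strictly increasing calibration levels in ng/mL. The
#'   default is the 12-level series 0.05--50 ng/mL.
#' @param ilis_tiers Allowed ILIS MIX tier concentrations (ng/mL).
#' @param ilis_spike_volume_uL ILIS MIX volume spiked per sample (µL).
#' @param soil_mass_g,extract_volume_mL Nominal sample intake and extract
#'   volume; with the default 5 g / 5 mL design, ng/mL in the extract and
#'   ng/g dry weight coincide.
#' @param rt_match_tol_min Retention-time identification tolerance (min).
#' @param recovery_band Acceptable relative-recovery band in percent.
#' @param linearity_tol_pct Allowed back-calculation deviation per
#'   calibration level in percent.
#' @param snr_quant_min,snr_qual_min Minimum signal-to-noise for the
#'   quantifier and qualifier transitions at the limit of quantification.
#' @param global_matrix_correction_factor Default factor applied to
#'   calibration-matrix-based MLOQs (see [derive_global_factor()]).
#'
#' @return An object of class `method_config`.
#' @seealso [read_method_config()], [simulate_method_config()]
#' @export
method_config <- function(analytes,
                          ilis,
                          transitions,
                          stereoisomers = NULL,
                          cal_levels = c(0.05, 0.1, 0.25, 0.5, 1, 2.5, 5, 10,
                                         17.5, 25, 35, 50),
                          ilis_tiers = c(50, 250, 750),
                          ilis_spike_volume_uL = 100,
                          soil_mass_g = 5,
                          extract_volume_mL = 5,
                          rt_match_tol_min = 0.05,
                          recovery_band = c(70, 120),
                          linearity_tol_pct = 20,
                          snr_quant_min = 10,
                          snr_qual_min = 3,
                          global_matrix_correction_factor = 2) {
  analytes <- tibble::as_tibble(analytes)
  ilis <- tibble::as_tibble(ilis)
  transitions <- tibble::as_tibble(transitions)
  for (col in c("stereoisomer_group", "si_ilis_id", "assigned_ilis_id")) {
    if (!col %in% names(analytes)) analytes[[col]] <- NA_character_
  }
  if (!is.null(stereoisomers)) stereoisomers <- tibble::as_tibble(stereoisomers)

  config <- structure(
    list(
      analytes = analytes,
      ilis = ilis,
      transitions = transitions,
      stereoisomers = stereoisomers,
      cal_levels = as.numeric(cal_levels),
      params = list(
        ilis_tiers = as.numeric(ilis_tiers),
        ilis_spike_volume_uL = as.numeric(ilis_spike_volume_uL),
        soil_mass_g = as.numeric(soil_mass_g),
        extract_volume_mL = as.numeric(extract_volume_mL),
        rt_match_tol_min = as.numeric(rt_match_tol_min),
        recovery_band = as.numeric(recovery_band),
        linearity_tol_pct = as.numeric(linearity_tol_pct),
        snr_quant_min = as.numeric(snr_quant_min),
        snr_qual_min = as.numeric(snr_qual_min),
        global_matrix_correction_factor =
          as.numeric(global_matrix_correction_factor)
      )
    ),
    class = "method_config"
  )
  validate_method_config(config)
}

pesticide_classes <- c(
  "fungicide", "herbicide", "insecticide", "acaricide", "rodenticide",
  "growth_regulator", "synergist", "transformation_product"
)

#' Validate a method configuration
#'
#' Checks identifier uniqueness, cross-references (analyte to ILIS, species
#' to transitions), polarity consistency between each analyte and its ILIS,
#' the one-quantifier-one-qualifier rule, ILIS tier membership and the
#' calibration-level ordering. Called by every constructor and reader;
#' exported so hand-edited configurations can be re-checked.
#'
#' @param config A `method_config`.
#' @return `config`, invisibly modified only in that structure-identical
#'   ILIS are copied into `assigned_ilis_id`.
#' @export
validate_method_config <- function(config) {
  an <- config$analytes
  il <- config$ilis
  tr <- config$transitions
  assert_columns(an, c("analyte_id", "name", "pesticide_class", "polarity",
                       "expected_rt"), "analyte catalog")
  assert_columns(il, c("ilis_id", "name", "polarity", "expected_rt",
                       "tier_concentration"), "ILIS catalog")
  assert_columns(tr, c("species_id", "role", "precursor_mz", "product_mz",
                       "polarity", "expected_rt"), "transition list")

  if (anyDuplicated(an$analyte_id)) {
    abort_soilmrm("Duplicate analyte_id in analyte catalog.",
                  "soilmrm_config_error")
  }
  if (anyDuplicated(il$ilis_id)) {
    abort_soilmrm("Duplicate ilis_id in ILIS catalog.",
                  "soilmrm_config_error")
  }
  if (length(intersect(an$analyte_id, il$ilis_id)) > 0L) {
    abort_soilmrm("analyte_id and ilis_id namespaces overlap.",
                  "soilmrm_config_error")
  }
  bad_class <- setdiff(unique(an$pesticide_class), pesticide_classes)
  if (length(bad_class) > 0L) {
    abort_soilmrm(
      sprintf("Unknown pesticide_class: %s", paste(bad_class, collapse = ", ")),
      "soilmrm_config_error"
    )
  }
  if (!all(il$tier_concentration %in% config$params$ilis_tiers)) {
    abort_soilmrm("ILIS tier_concentration outside the configured tier set.",
                  "soilmrm_validation_error")
  }

  # structure-identical ILIS pin the assignment
  has_si <- !is.na(an$si_ilis_id)
  unknown_si <- setdiff(an$si_ilis_id[has_si], il$ilis_id)
  if (length(unknown_si) > 0L) {
    abort_soilmrm(
      sprintf("Analyte references unknown ILIS: %s",
              paste(unknown_si, collapse = ", ")),
      "soilmrm_reference_error"
    )
  }
  an$assigned_ilis_id[has_si] <- an$si_ilis_id[has_si]
  has_asg <- !is.na(an$assigned_ilis_id)
  unknown_asg <- setdiff(an$assigned_ilis_id[has_asg], il$ilis_id)
  if (length(unknown_asg) > 0L) {
    abort_soilmrm(
      sprintf("Assigned ILIS not in catalog: %s",
              paste(unknown_asg, collapse = ", ")),
      "soilmrm_reference_error"
    )
  }
  if (any(has_asg)) {
    pol_ilis <- il$polarity[match(an$assigned_ilis_id[has_asg], il$ilis_id)]
    if (any(pol_ilis != an$polarity[has_asg])) {
      abort_soilmrm(
        "Polarity mismatch between analyte and its assigned ILIS.",
        "soilmrm_validation_error"
      )
    }
  }

  # measured species: analytes (or their stereoisomer peaks) plus ILIS
  species <- measured_species(config)
  if (!is.null(config$stereoisomers)) {
    st <- config$stereoisomers
    assert_columns(st, c("species_id", "analyte_id"), "stereoisomer table")
    if (anyDuplicated(st$species_id)) {
      abort_soilmrm("Duplicate species_id in stereoisomer table.",
                    "soilmrm_config_error")
    }
    if (!all(st$analyte_id %in% an$analyte_id)) {
      abort_soilmrm("Stereoisomer table references unknown analyte.",
                    "soilmrm_reference_error")
    }
  }

  if (!all(tr$role %in% c("quantifier", "qualifier"))) {
    abort_soilmrm("Transition role must be 'quantifier' or 'qualifier'.",
                  "soilmrm_validation_error")
  }
  if (any(tr$precursor_mz <= 0) || any(tr$product_mz <= 0)) {
    abort_soilmrm("Transition m/z values must be positive.",
                  "soilmrm_validation_error")
  }
  counts <- table(tr$species_id, tr$role)
  if (!setequal(rownames(counts), species) ||
      any(counts != 1L)) {
    abort_soilmrm(
      "Each measured species needs exactly one quantifier and one qualifier transition.",
      "soilmrm_validation_error"
    )
  }

  if (length(config$cal_levels) < 2L ||
      any(diff(config$cal_levels) <= 0) || any(config$cal_levels <= 0)) {
    abort_soilmrm("cal_levels must be positive and strictly increasing.",
                  "soilmrm_validation_error")
  }
  band <- config$params$recovery_band
  if (length(band) != 2L || band[1] >= band[2]) {
    abort_soilmrm("recovery_band must be (low, high) with low < high.",
                  "soilmrm_validation_error")
  }

  config$analytes <- an
  config
}

# All species that carry transitions: stereoisomer member peaks replace
# their parent analyte; ILIS are always measured directly.
measured_species <- function(config) {
  an_ids <- config$analytes$analyte_id
  if (!is.null(config$stereoisomers) && nrow(config$stereoisomers) > 0L) {
    parents <- unique(config$stereoisomers$analyte_id)
    an_ids <- c(setdiff(an_ids, parents), config$stereoisomers$species_id)
  }
  c(an_ids, config$ilis$ilis_id)
}

# Measurement species belonging to one analyte (itself, or its
# stereoisomer member peaks when those are integrated separately).
analyte_species <- function(config, analyte_id) {
  st <- config$stereoisomers
  if (!is.null(st) && analyte_id %in% st$analyte_id) {
    st$species_id[st$analyte_id == analyte_id]
  } else {
    analyte_id
  }
}

#' @export
print.method_config <- function(x, ...) {
  n_si <- sum(!is.na(x$analytes$si_ilis_id))
  n_asg <- sum(!is.na(x$analytes$assigned_ilis_id))
  cat("<method_config>\n")
  cat(sprintf("  analytes:    %d (%d with structure-identical ILIS, %d assigned)\n",
              nrow(x$analytes), n_si, n_asg))
  cat(sprintf("  ILIS:        %d\n", nrow(x$ilis)))
  cat(sprintf("  transitions: %d\n", nrow(x$transitions)))
  cat(sprintf("  calibration: %d levels, %.3g-%.3g ng/mL\n",
              length(x$cal_levels), min(x$cal_levels), max(x$cal_levels)))
  invisible(x)
}

#' Read and write method configurations
#'
#' Configurations are serialised to JSON or YAML (chosen by file extension).
#' `write_method_config()` followed by `read_method_config()` is the
#' identity on all fields.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @param config A `method_config`.
#' @return `read_method_config()` returns a validated `method_config`;
#'   `write_method_config()` returns `path` invisibly.
#' @export
read_method_config <- function(path) {
  if (!file.exists(path)) {
    abort_soilmrm(sprintf("Config file not found: %s", path),
                  "soilmrm_config_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    abort_soilmrm("Config must be .json, .yaml or .yml.",
                  "soilmrm_config_error")
  )
  as_cfg_tbl <- function(x) {
    df <- tibble::as_tibble(as.data.frame(x, stringsAsFactors = FALSE))
    df[] <- lapply(df, function(col) {
      if (is.logical(col) && all(is.na(col))) NA_character_ else col
    })
    df
  }
  p <- raw$params
  method_config(
    analytes = as_cfg_tbl(raw$analytes),
    ilis = as_cfg_tbl(raw$ilis),
    transitions = as_cfg_tbl(raw$transitions),
    stereoisomers = if (!is.null(raw$stereoisomers) &&
                        NROW(raw$stereoisomers) > 0L) {
      as_cfg_tbl(raw$stereoisomers)
    },
    cal_levels = as.numeric(raw$cal_levels),
    ilis_tiers = as.numeric(p$ilis_tiers),
    ilis_spike_volume_uL = p$ilis_spike_volume_uL,
    soil_mass_g = p$soil_mass_g,
    extract_volume_mL = p$extract_volume_mL,
    rt_match_tol_min = p$rt_match_tol_min,
    recovery_band = as.numeric(p$recovery_band),
    linearity_tol_pct = p$linearity_tol_pct,
    snr_quant_min = p$snr_quant_min,
    snr_qual_min = p$snr_qual_min,
    global_matrix_correction_factor = p$global_matrix_correction_factor
  )
}

#' @rdname read_method_config
#' @export
write_method_config <- function(config, path) {
  stopifnot(inherits(config, "method_config"))
  payload <- list(
    analytes = config$analytes,
    ilis = config$ilis,
    transitions = config$transitions,
    stereoisomers = config$stereoisomers,
    cal_levels = config$cal_levels,
    params = config$params
  )
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    payload$analytes <- as.data.frame(payload$analytes)
    payload$ilis <- as.data.frame(payload$ilis)
    payload$transitions <- as.data.frame(payload$transitions)
    if (!is.null(payload$stereoisomers)) {
      payload$stereoisomers <- as.data.frame(payload$stereoisomers)
    }
    yaml::write_yaml(payload, path)
  } else {
    abort_soilmrm("Config must be .json, .yaml or .yml.",
                  "soilmrm_config_error")
  }
  invisible(path)
}

#' Import catalogs from CSV files
#'
#' Vendor-agnostic import path: one CSV row per species for the analyte and
#' ILIS catalogs and one row per transition, with the same column names the
#' tibble constructors expect. Method parameters take their defaults and can
#' be overridden through `...` (passed to [method_config()]).
#'
#' @param analytes_csv,ilis_csv,transitions_csv CSV paths (UTF-8, `.`
#'   decimal separator).
#' @param stereoisomers_csv Optional CSV mapping stereoisomer peaks.
#' @param ... Further arguments to [method_config()].
#' @return A validated `method_config`.
#' @export
read_catalog_csv <- function(analytes_csv, ilis_csv, transitions_csv,
                             stereoisomers_csv = NULL, ...) {
  read_one <- function(path) {
    df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    df[] <- lapply(df, function(col) {
      if (is.character(col)) replace(col, col == "", NA_character_) else col
    })
    df
  }
  method_config(
    analytes = read_one(analytes_csv),
    ilis = read_one(ilis_csv),
    transitions = read_one(transitions_csv),
    stereoisomers = if (!is.null(stereoisomers_csv)) read_one(stereoisomers_csv),
    ...
  )
}

#' Dry-weight equivalent of a soil aliquot
#'
#' Undried field soils are weighed in with their residual water; reported
#' concentrations refer to dry weight, so the intake mass is corrected by
#' the determined water content.
#'
#' @param mass_g Weighed-in soil mass (g).
#' @param water_content_pct Gravimetric water content in percent
#'   (0 for dried soil); must be below 100.
#' @return Dry mass in grams: `mass_g * (1 - water_content_pct / 100)`.
#' @examples
#' dry_weight_equivalent(5, 0)
#' dry_weight_equivalent(6.25, 20)
#' @export
dry_weight_equivalent <- function(mass_g, water_content_pct) {
  if (any(water_content_pct < 0) || any(water_content_pct >= 100)) {
    abort_soilmrm("water_content_pct must be in [0, 100).",
                  "soilmrm_domain_error")
  }
  if (any(mass_g < 0)) {
    abort_soilmrm("mass_g must be non-negative.", "soilmrm_domain_error")
  }
  mass_g * (1 - water_content_pct / 100)
}

#' Final ILIS concentration in the measurement extract
#'
#' A fixed volume of the ILIS MIX solution is spiked per sample; in the
#' final extract each ILIS sits at `tier_ng_mL * spike_volume_uL / 1000 /
#' extract_volume_mL`. With the default 100 µL spike into a 5 mL extract the
#' 50/250/750 ng/mL tiers give 1, 5 and 15 ng/mL.
#'
#' @param tier_ng_mL ILIS MIX tier concentration (ng/mL).
#' @param spike_volume_uL Spiked MIX volume (µL).
#' @param extract_volume_mL Final extract volume (mL).
#' @return Concentration in ng/mL.
#' @examples
#' ilis_standard_concentration(750, 100, 5)
#' @export
ilis_standard_concentration <- function(tier_ng_mL, spike_volume_uL,
                                        extract_volume_mL) {
  assert_number(spike_volume_uL, "spike_volume_uL", lower = 0)
  assert_number(extract_volume_mL, "extract_volume_mL",
                lower = .Machine$double.eps)
  tier_ng_mL * (spike_volume_uL / 1000) / extract_volume_mL
}
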