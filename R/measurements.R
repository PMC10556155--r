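#' Read and validate a long-format measurement table
#'
#' The canonical measurement interchange is a long-format CSV with one row
#' per sample x transition: `sample_id, species_id, transition_role,
#' peak_area, snr, rt`. Peak integration happens in the acquisition
#' software; areas and signal-to-noise ratios are inputs here, never
#' recomputed. A transition that was not detected is represented with
#' `peak_area = 0` and `snr = 0`, not by a missing row.
#'
#' @param path CSV file (UTF-8, `.` decimal separator). Alternative vendor
#'   headers can be mapped through `column_map`.
#' @param config A `method_config`; rows with species not in the method are
#'   rejected.
#' @param design Optional batch design; when given, measurement samples
#'   absent from the design raise an orphan-sample error.
#' @param column_map Named character vector mapping canonical column names
#'   to the names used in the file, e.g.
#'   `c(peak_area = "Area", snr = "Signal.Noise")`.
#' @return A validated measurement tibble.
#' @export
read_measurements <- function(path, config, design = NULL, column_map = NULL) {
  if (!file.exists(path)) {
    abort_soilmrm(sprintf("Measurement file not found: %s", path),
                  "soilmrm_config_error")
  }
  tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      vendor <- column_map[[canonical]]
      if (vendor %in% names(tbl)) {
        names(tbl)[names(tbl) == vendor] <- canonical
      }
    }
  }
  validate_measurements(tbl, config, design)
}

#' @rdname read_measurements
#' @param measurements A measurement tibble.
#' @export
validate_measurements <- function(measurements, config, design = NULL) {
  assert_columns(measurements,
                 c("sample_id", "species_id", "transition_role", "peak_area",
                   "snr", "rt"),
                 "measurement table")
  species <- measured_species(config)
  unknown <- setdiff(unique(measurements$species_id), species)
  if (length(unknown) > 0L) {
    abort_soilmrm(sprintf("Measurements reference unknown species: %s",
                          paste(utils::head(unknown, 5), collapse = ", ")),
                  "soilmrm_reference_error")
  }
  if (!all(measurements$transition_role %in% c("quantifier", "qualifier"))) {
    abort_soilmrm("transition_role must be 'quantifier' or 'qualifier'.",
                  "soilmrm_validation_error")
  }
  if (any(measurements$peak_area < 0) || any(measurements$snr < 0)) {
    abort_soilmrm("peak_area and snr must be non-negative.",
                  "soilmrm_validation_error")
  }
  key <- paste(measurements$sample_id, measurements$species_id,
               measurements$transition_role, sep = "\x1f")
  if (anyDuplicated(key)) {
    abort_soilmrm("Duplicated (sample, species, transition_role) rows.",
                  "soilmrm_validation_error")
  }
  if (!is.null(design)) {
    orphans <- setdiff(unique(measurements$sample_id), design$sample_id)
    if (length(orphans) > 0L) {
      abort_soilmrm(
        sprintf("Samples present in measurements but absent from the batch design: %s",
                paste(utils::head(orphans, 5), collapse = ", ")),
        "soilmrm_orphan_sample_error"
      )
    }
  }
  measurements
}

#' @rdname read_measurements
#' @export
write_measurements <- function(measurements, path) {
  cols <- c("sample_id", "species_id", "transition_role", "peak_area",
            "snr", "rt")
  utils::write.csv(measurements[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
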