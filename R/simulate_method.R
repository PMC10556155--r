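#' Simulate a multi-residue method catalog
#'
#' Builds a complete `method_config` with the structure of a large targeted
#' soil multi-residue method: `n_analytes` pesticides across the usual
#' class composition (fungicides, herbicides, insecticides, acaricides,
#' rodenticides, growth regulators, synergists, transformation products),
#' `n_ilis` isotope-labeled internal standards each structure-identical to
#' one analyte, and one quantifier plus one qualifier MRM transition per
#' measured species. The default sizes mirror a 146-analyte / 95-ILIS
#' method, so 51 analytes lack a structure-identical ILIS and must be
#' assigned one (see [assign_ilis()]). A configurable number of ILIS and of
#' the remaining analytes ionize in negative mode (8 and 11 by default);
#' everything else is positive mode.
#'
#' @param n_analytes,n_ilis Catalog sizes; `n_ilis <= n_analytes`.
#' @param n_negative_ilis Number of negative-mode ILIS (these are the
#'   structure-identical partners of the first negative-mode analytes).
#' @param n_negative_nsi Number of negative-mode analytes without
#'   structure-identical ILIS.
#' @param n_stereoisomer_analytes Number of analytes measured as two
#'   chromatographically separated stereoisomer peaks whose areas are
#'   summed.
#' @param rt_range Retention-time range (minutes) of the chromatographic
#'   run over which species elute.
#' @param seed Integer seed; the catalog is reproducible bit for bit.
#' @param ... Passed to [method_config()] (calibration levels, tolerances).
#' @return A validated `method_config`.
#' @examples
#' cfg <- simulate_method_config(n_analytes = 10, n_ilis = 6, seed = 1)
#' cfg
#' @export
simulate_method_config <- function(n_analytes = 146,
                                   n_ilis = 95,
                                   n_negative_ilis = 8,
                                   n_negative_nsi = 11,
                                   n_stereoisomer_analytes = 0,
                                   rt_range = c(2, 28),
                                   seed = 101,
                                   ...) {
  stopifnot(n_ilis <= n_analytes,
            n_negative_ilis <= n_ilis,
            n_negative_nsi <= n_analytes - n_ilis,
            n_stereoisomer_analytes <= n_analytes)
  with_seed(hash_seed(seed, "method_config"), {
    class_quota <- c(
      fungicide = 60, herbicide = 30, insecticide = 26, acaricide = 4,
      rodenticide = 4, growth_regulator = 2, synergist = 1,
      transformation_product = 19
    )
    classes <- rep(names(class_quota), class_quota)
    classes <- rep_len(classes, n_analytes)

    analyte_id <- sprintf("A%03d", seq_len(n_analytes))
    rt <- stats::runif(n_analytes, rt_range[1], rt_range[2])
    polarity <- rep("positive", n_analytes)
    if (n_negative_ilis > 0) {
      polarity[seq_len(n_negative_ilis)] <- "negative"
    }
    if (n_negative_nsi > 0) {
      polarity[n_ilis + seq_len(n_negative_nsi)] <- "negative"
    }

    si_ilis_id <- rep(NA_character_, n_analytes)
    si_ilis_id[seq_len(n_ilis)] <- sprintf("IL%03d", seq_len(n_ilis))

    analytes <- tibble::tibble(
      analyte_id = analyte_id,
      name = sprintf("pesticide-%03d", seq_len(n_analytes)),
      pesticide_class = classes,
      polarity = polarity,
      expected_rt = round(rt, 3),
      stereoisomer_group = NA_character_,
      si_ilis_id = si_ilis_id,
      assigned_ilis_id = NA_character_
    )

    ilis_rt <- pmin(pmax(rt[seq_len(n_ilis)] +
                           stats::rnorm(n_ilis, 0.07, 0.03),
                         rt_range[1]), rt_range[2])
    ilis <- tibble::tibble(
      ilis_id = sprintf("IL%03d", seq_len(n_ilis)),
      name = sprintf("pesticide-%03d-label", seq_len(n_ilis)),
      polarity = polarity[seq_len(n_ilis)],
      expected_rt = round(ilis_rt, 3),
      tier_concentration = sample(c(50, 250, 750), n_ilis, replace = TRUE)
    )

    stereoisomers <- NULL
    if (n_stereoisomer_analytes > 0) {
      # stereoisomer pairs go on late-eluting analytes with si-ILIS so the
      # summed-PAR path is exercised without touching the assignment set
      parents <- analyte_id[order(rt)[seq_len(n_stereoisomer_analytes)]]
      stereoisomers <- tibble::tibble(
        species_id = c(paste0(parents, "a"), paste0(parents, "b")),
        analyte_id = rep(parents, 2)
      )
      analytes$stereoisomer_group[match(parents, analytes$analyte_id)] <-
        parents
    }

    species <- tibble::tibble(
      species_id = c(
        setdiff(analyte_id, stereoisomers$analyte_id %||% character()),
        stereoisomers$species_id %||% character(),
        ilis$ilis_id
      )
    )
    base_of <- function(sid) {
      hit <- match(sid, stereoisomers$species_id %||% character())
      ifelse(is.na(hit), sid, stereoisomers$analyte_id[hit])
    }
    base_ids <- base_of(species$species_id)
    all_rt <- c(stats::setNames(analytes$expected_rt, analytes$analyte_id),
                stats::setNames(ilis$expected_rt, ilis$ilis_id))
    all_pol <- c(stats::setNames(analytes$polarity, analytes$analyte_id),
                 stats::setNames(ilis$polarity, ilis$ilis_id))
    sp_rt <- unname(all_rt[base_ids])
    # separated stereoisomer peaks elute slightly apart
    is_member <- species$species_id %in% (stereoisomers$species_id %||% character())
    sp_rt[is_member] <- sp_rt[is_member] +
      ifelse(grepl("a$", species$species_id[is_member]), -0.15, 0.15)

    n_sp <- nrow(species)
    transitions <- tibble::tibble(
      species_id = rep(species$species_id, each = 2),
      role = rep(c("quantifier", "qualifier"), n_sp),
      precursor_mz = round(rep(stats::runif(n_sp, 150, 500), each = 2), 1),
      polarity = rep(unname(all_pol[base_ids]), each = 2),
      expected_rt = rep(round(sp_rt, 3), each = 2)
    )
    transitions$product_mz <- round(
      stats::runif(2 * n_sp, 50, transitions$precursor_mz - 20), 1
    )
    transitions <- transitions[, c("species_id", "role", "precursor_mz",
                                   "product_mz", "polarity", "expected_rt")]

    method_config(
      analytes = analytes,
      ilis = ilis,
      transitions = transitions,
      stereoisomers = stereoisomers,
      ...
    )
  })
}
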