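#' Relative recovery of a spiked sample
#'
#' ILIS-corrected concentration recovered from a freshly spiked soil,
#' native background subtracted: `100 * (conc_spiked - conc_unspiked) /
#' spike_level`. Adding the same native residue to both preparations
#' leaves the result unchanged by construction. Because analyte and a
#' pre-extraction-spiked ILIS lose mass together, relative recoveries
#' center on 100% even when the extraction itself recovers less — the
#' rationale for spiking the ILIS before extraction.
#'
#' @param conc_spiked,conc_unspiked ILIS-corrected concentrations (ng/g
#'   dry weight) of the spiked and unspiked preparations.
#' @param spike_level Spiked concentration (ng/g dry weight), > 0.
#' @return Recovery in percent, vectorised.
#' @examples
#' relative_recovery(3.0, 0.5, 2.5)
#' @export
relative_recovery <- function(conc_spiked, conc_unspiked, spike_level) {
  if (any(!is.finite(spike_level)) || any(spike_level <= 0)) {
    abort_soilmrm("spike_level must be positive.", "soilmrm_domain_error")
  }
  100 * (conc_spiked - conc_unspiked) / spike_level
}

#' Absolute extraction recovery (pre- vs post-extraction spike)
#'
#' Extraction efficiency measured on uncorrected analyte responses: the
#' blank-subtracted peak area of a sample spiked before extraction
#' relative to one spiked into the final extract at the same nominal
#' level, `100 * (pre - blank) / (post - blank)`. Unlike relative
#' recovery, no ILIS compensation is involved, so losses during
#' extraction show up directly.
#'
#' @param pre_spike,post_spike,blank Quantifier peak areas (or area means)
#'   of the pre-extraction spike, post-extraction spike and unspiked
#'   blank. Blank subtraction can be disabled by passing `blank = 0`.
#' @return Recovery in percent; `NA` with a warning where
#'   `post_spike <= blank`.
#' @examples
#' absolute_recovery_quechers(900, 1000, 100)
#' @export
absolute_recovery_quechers <- function(pre_spike, post_spike, blank = 0) {
  denom <- post_spike - blank
  out <- 100 * (pre_spike - blank) / denom
  if (any(denom <= 0)) {
    warning("post_spike <= blank: absolute recovery undefined, returning NA.")
    out[denom <= 0] <- NA_real_
  }
  out
}

precision_tiers <- c("instrumental", "intra_day", "inter_day",
                     "inter_person")

#' Precision as relative standard deviation at a tier's aggregation level
#'
#' Four precision tiers share one statistic, `RSD = 100 * sd / mean`
#' (sample standard deviation), applied at different aggregation levels:
#'
#' * `instrumental` — repeated injections of one extract (n >= 3);
#' * `intra_day` — replicate sample preparations within one day (n >= 3),
#'   computed on the raw replicate values;
#' * `inter_day` — repeated preparations across days, computed on the
#'   day-level means (>= 3 days; `grouping` gives the day label per
#'   value);
#' * `inter_person` — computed on operator-level means (>= 2 operators).
#'
#' @param values Numeric replicate values (concentrations or responses).
#' @param tier One of `"instrumental"`, `"intra_day"`, `"inter_day"`,
#'   `"inter_person"`.
#' @param grouping Day or operator label per value; required for the
#'   `inter_day` and `inter_person` tiers.
#' @return A list: `tier`, `rsd_pct`, `n`, `n_groups`. `rsd_pct` is `NA`
#'   with a warning when the mean is zero.
#' @examples
#' precision(c(9, 10, 11), "intra_day")
#' @export
precision <- function(values, tier = precision_tiers, grouping = NULL) {
  tier <- match.arg(tier)
  n_groups <- NA_integer_
  if (tier %in% c("inter_day", "inter_person")) {
    if (is.null(grouping) || length(grouping) != length(values)) {
      abort_soilmrm("inter_day / inter_person precision needs a grouping label per value.",
                    "soilmrm_validation_error")
    }
    agg <- tapply(values, grouping, mean)
    n_groups <- length(agg)
    min_groups <- if (tier == "inter_day") 3L else 2L
    if (n_groups < min_groups) {
      abort_soilmrm(sprintf("%s precision needs >= %d groups.", tier,
                            min_groups),
                    "soilmrm_validation_error")
    }
    values <- as.numeric(agg)
  } else {
    if (length(values) < 3L) {
      abort_soilmrm(sprintf("%s precision needs >= 3 values.", tier),
                    "soilmrm_validation_error")
    }
  }
  m <- mean(values)
  if (m == 0) {
    warning("Mean is zero: RSD undefined, returning NA.")
    rsd <- NA_real_
  } else {
    rsd <- 100 * stats::sd(values) / m
  }
  list(tier = tier, rsd_pct = rsd, n = length(values), n_groups = n_groups)
}

#' Trueness against an aged reference soil
#'
#' Per-analyte deviation of the measured concentration from its target
#' (the nominal spike or a long-term mean), `100 * (measured - target) /
#' target`, and the fraction of analytes deviating beyond the tolerance
#' band. Deviations beyond the band are expected for analytes prone to
#' fast degradation or strong aging in the reference material, so they
#' are reported, not errors.
#'
#' @param measured Tibble `analyte_id, conc_ng_g` (replicate-averaged).
#' @param target Either a single target concentration (ng/g) for all
#'   analytes or a tibble `analyte_id, target_ng_g`.
#' @param tol_pct Tolerance band in percent (default 20).
#' @return A list: `per_analyte` (tibble with `deviation_pct`,
#'   `within_band`) and `fraction_beyond` (share with
#'   `|deviation| > tol_pct`).
#' @export
trueness_vs_reference <- function(measured, target, tol_pct = 20) {
  assert_columns(measured, c("analyte_id", "conc_ng_g"),
                 "measured concentrations")
  if (is.numeric(target) && length(target) == 1L) {
    target <- tibble::tibble(analyte_id = measured$analyte_id,
                             target_ng_g = target)
  }
  assert_columns(target, c("analyte_id", "target_ng_g"), "target table")
  df <- dplyr::inner_join(measured, target, by = "analyte_id")
  df$deviation_pct <- 100 * (df$conc_ng_g - df$target_ng_g) / df$target_ng_g
  df$within_band <- abs(df$deviation_pct) <= tol_pct
  list(
    per_analyte = df[, c("analyte_id", "conc_ng_g", "target_ng_g",
                         "deviation_pct", "within_band")],
    fraction_beyond = mean(!df$within_band)
  )
}

#' Proficiency z-scores against a peer panel
#'
#' Robust z-score of a laboratory result against the peer consensus:
#' `z = (x_lab - median(peers)) / (1.4826 * MAD(peers))`, the
#' median/scaled-MAD simplification of the robust assigned value and
#' proficiency standard deviation. `|z| <= 1` is labeled good,
#' `<= 2` satisfactory, `<= 3` questionable, otherwise unsatisfactory.
#' Panels smaller than 8 peers are flagged (`small_panel`): very small
#' panels call for dedicated small-n procedures.
#'
#' @param x_lab Laboratory value(s), one per analyte.
#' @param peers A list of numeric peer-value vectors (one per analyte,
#'   each n >= 4), or a single numeric vector when scoring one analyte.
#' @return Tibble `z, label, sigma_pt, n_peers, small_panel`; `z` is `NA`
#'   with label `"undefined"` where the peer MAD is zero.
#' @examples
#' z_scores(13, c(8, 9, 10, 11, 12))
#' @export
z_scores <- function(x_lab, peers) {
  if (is.numeric(peers)) peers <- list(peers)
  stopifnot(length(x_lab) == length(peers))
  rows <- lapply(seq_along(peers), function(i) {
    p <- peers[[i]]
    if (length(p) < 4L) {
      abort_soilmrm("z-scores need >= 4 peer values per analyte.",
                    "soilmrm_validation_error")
    }
    sigma <- stats::mad(p, constant = 1.4826)
    z <- if (sigma > 0) (x_lab[i] - stats::median(p)) / sigma else NA_real_
    label <- if (is.na(z)) {
      "undefined"
    } else if (abs(z) <= 1) {
      "good"
    } else if (abs(z) <= 2) {
      "satisfactory"
    } else if (abs(z) <= 3) {
      "questionable"
    } else {
      "unsatisfactory"
    }
    tibble::tibble(z = z, label = label, sigma_pt = sigma,
                   n_peers = length(p), small_panel = length(p) < 8L)
  })
  dplyr::bind_rows(rows)
}
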