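# soilmrm

Quantification and quality control for targeted LC-MS/MS (MRM)
multi-residue pesticide monitoring in soils.

Routine soil monitoring quantifies a hundred or more pesticides per
extract at sub-ng/g levels. Two features make the data processing
non-trivial: electrospray ionisation is suppressed (occasionally
enhanced) by co-extracted matrix constituents, and the degree of
suppression varies with the soil — in particular with its organic-carbon
content. The established countermeasures, which this package implements
as a reusable pipeline for people running such monitoring programmes,
are:

* **Matrix-matched internal-standard calibration.** The response
  variable is the peak-area ratio PAR = A_analyte / A_ILIS (ILIS:
  isotope-labeled internal standard, spiked onto every sample before
  extraction). Calibration standards are prepared in a blank soil
  extract and fitted by linear least squares with 1/x weighting:
  minimise Σ wᵢ (PARᵢ − a − b·xᵢ)², wᵢ = 1/xᵢ. Linearity is reviewed per
  level by back-calculation (|deviation| ≤ 20%), trimming only the range
  edges.
* **Identification gating.** A detection is reportable only if its
  retention time matches the co-acquired standards within ±0.05 min and
  its qualifier-to-quantifier ion ratio falls within the banded
  tolerances of Directive 2002/657/EC (±20/25/30/50% for reference
  ratios >0.5 / >0.2 / >0.1 / ≤0.1).
* **Matrix effects and the global correction factor.** Per analyte and
  soil, ME[%] = (1 − (PA_spiked − PA_unspiked)/PA_reference)·(−100),
  with either a solvent standard (case i) or the calibration-matrix net
  response (case ii) as reference; negative values are ion suppression.
  Method LOQs determined in the calibration matrix are inflated by a
  single factor 1/(1 − s/100), where s is the smallest grid suppression
  leaving at most a configured number of analytes uncovered (s = 50%
  gives the factor 2).
* **Limits of quantification.** ILOQ/MLOQ are the lowest solvent / 
  matrix-matched levels with quantifier S/N ≥ 10, qualifier S/N ≥ 3 and
  (for MLOQ) a conforming ion ratio; quantified concentrations are
  reported in ng/g dry weight and censored against the corrected MLOQ
  and the linear range.
* **Systematic surrogate-ILIS assignment.** Analytes without a
  structure-identical ILIS are assigned one by screening all
  same-polarity candidates (within ±2 min retention time in positive
  mode) for relative recoveries across soils, maximising the number of
  soils in the 70–120% band with deterministic tie-breaks.
* **Figures of merit.** Absolute (pre- vs post-extraction spike) and
  relative (ILIS-corrected) recoveries, four precision tiers (RSD at the
  appropriate aggregation level), trueness against an aged reference
  soil, and robust (median/MAD) proficiency z-scores.

Because raw instrument data of such monitoring methods are rarely
shareable, the package ships a first-class synthetic batch generator
(`simulate_batch()`) with known ground truth — organic-carbon-dependent
suppression, retention-time-correlated ILIS compensation, extraction
losses, aging, replicate noise — so the entire pipeline is testable end
to end.

## Worked example

Simulate a small 12-analyte method (8 with structure-identical ILIS),
generate a validation batch, and process it:

```r
library(soilmrm)

config   <- simulate_method_config(n_analytes = 12, n_ilis = 8,
                                   n_negative_ilis = 2, n_negative_nsi = 2,
                                   seed = 42)
config
#> <method_config>
#>   analytes:    12 (8 with structure-identical ILIS, 8 assigned)
#>   ILIS:        8
#>   transitions: 40
#>   calibration: 12 levels, 0.05-50 ng/mL

scenario <- sim_scenario(seed = 7)   # 3% area noise, suppression -8%/%C_org
res      <- run_validation_batch(config, scenario)

res$curves[, c("analyte_id", "ilis_id", "slope", "r_squared",
               "linear_low", "linear_high")]
#> # A tibble: 8 x 6
#>   analyte_id ilis_id  slope r_squared linear_low linear_high
#> 1 A001       IL001   0.0875     0.999       0.05          50
#> 2 A002       IL002   0.611      0.999       0.05          50
#> ...

res$mloq
#> # A tibble: 12 x 5
#>   analyte_id base_mloq_ng_g determined corrected_mloq_ng_g factor_used
#> 1 A001                 0.05 TRUE                       0.1           2
#> ...

res$factor$factor     # global matrix correction factor derived from case (ii)
#> [1] 2
```

The per-analyte curves back-calculate every level within the 20%
linearity tolerance (weighted R² ≈ 0.999), the base MLOQs snap to the
lowest qualifying calibration level (0.05 ng/g here) and are doubled by
the derived factor, and the 2.5 ng/g pre-extraction spikes quantify at a
median 100.4% of their nominal value — the ILIS cancels both the
extraction losses and the soil-specific ion suppression the generator
injected.

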