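---
title: "Methods: matrix-matched ILIS quantification and QC for soil multi-residue data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matrix-matched ILIS quantification and QC for soil multi-residue data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilmrm)
```

## The quantification model

Targeted soil residue analysis monitors two MRM transitions per compound
(a sensitive *quantifier* and a confirmatory *qualifier*) for every
analyte and every isotope-labeled internal standard (ILIS). The
calibration response is the peak-area ratio

$$\mathrm{PAR} = \frac{\sum_{\text{stereoisomer peaks}} A_{\text{quantifier}}}{A_{\text{ILIS quantifier}}},$$

with chromatographically separated stereoisomers integrated and summed
before the ratio is formed. Per analyte, `fit_calibration()` solves the
weighted least-squares problem

$$\min_{a,b} \sum_i w_i\,(\mathrm{PAR}_i - a - b\,x_i)^2,
  \qquad w_i = 1/x_i,$$

over the matrix-matched standards ($x$ in ng/mL; twelve levels
0.05–50 ng/mL by default, replicate injections as individual points).
The 1/x weighting balances the relative influence of levels across the
three decades the series spans; an unweighted fit would be dominated by
the top levels and bias the back-calculation of the sub-ng/mL levels
where residue findings concentrate. Quantified extract concentrations,
$(\mathrm{PAR}-a)/b$, convert to soil concentrations via

$$c_{\text{soil}}\ [\text{ng/g dw}] = c_{\text{extract}}
  \cdot \frac{V_{\text{extract}}}{m_{\text{soil}} (1 - w/100)},$$

so with the default 5 g / 5 mL design the two scales coincide and an
undried sample is handled through its water content $w$
(`dry_weight_equivalent()`).

Assumptions worth stating explicitly: the response is linear in
concentration over the reported range (reviewed, not assumed — see
below); the ILIS experiences the same matrix effect and extraction loss
as its analyte (exactly true for a structure-identical ILIS, and
approximately true for a surrogate eluting nearby, which is what the
assignment module optimises); and peak integration, including S/N
estimation, happens upstream in acquisition software — peak areas and
S/N are *inputs*, and this package deliberately contains no
chromatogram processing.

## Linearity review and the linear range

`review_linearity()` back-calculates each level and passes it when
$|c_{\text{back}} - x|/x \le 20\%$ (boundary inclusive). Failing levels
are removed only from the edges of the series (contiguous trimming) and
the curve is refitted on the trimmed set; an interior failure is
flagged for review but does not split the range, because a single
linear range per analyte is what a monitoring report carries. The lower
edge is additionally constrained to levels meeting the S/N and
ion-ratio rules (below), so the reported range never starts below the
analyte's quantifiable region.

Two choices here were genuinely open and are resolved as follows. The
reported $R^2$ is computed on the weighted residuals, consistent with
the fit that produced them (the unweighted $R^2$ is kept alongside in
`r_squared_unweighted`). The intercept is estimated rather than forced
through zero: a zero-intercept model would silently absorb any blank
contribution into the slope.

## Identification gating

`check_identification()` requires, per candidate detection:

* retention time within ±0.05 min (inclusive, with a 1 ns-scale epsilon
  so a shift of exactly the tolerance passes despite floating-point
  representation) of the analyte's retention time in the co-acquired
  matrix-matched standards — by default the batch-mean standard RT; a
  nearest-in-injection-order mode is available when the design carries
  an `injection_order` column;
* a qualifier-to-quantifier ratio within the banded relative tolerance
  of the reference ratio (the mean over all standards of the sequence
  with both transitions detected): ±20% above 0.5, ±25% in (0.2, 0.5],
  ±30% in (0.1, 0.2], ±50% at or below 0.1. Band boundaries are closed
  on the lower band (a reference ratio of exactly 0.5 gets ±25%); the
  directive text does not fix the convention, so it is configurable
  (`boundaries = "upper"`).

A missing qualifier fails the gate with its own reason code. Failed
detections are censored `unconfirmed` — reported, never silently
dropped.

## Matrix effects, the global correction factor, and LOQs

`matrix_effect()` implements

$$\mathrm{ME}\,[\%] = \left(1 -
  \frac{\overline{PA}_{\text{spiked}} - \overline{PA}_{\text{unspiked}}}
       {\text{reference}}\right)\cdot(-100),$$

with the solvent standard (case i) or the calibration matrix's own net
response (case ii) as reference; negative values are ion suppression.
The case-i reference is restricted to solvent standards at the spike
level itself, so a co-acquired dilution series cannot contaminate the
reference mean. Applied to the calibration matrix with itself as
reference the formula returns exactly zero — a useful identity test.

`derive_global_factor()` turns the case-ii distribution into a single
MLOQ inflation factor: the smallest grid suppression $s$ (default grid
0–95% in 5% steps) such that at most `max_exceedances` analytes
(default 3) show stronger suppression in *any* soil, then
$f = 1/(1-s/100)$ rounded **up** to 0.5 — conservative by design, since
the factor's job is to keep reported limits honest across unseen soils.
Counting is per analyte (worst soil) by default, matching how such
exceedances are described in validation reports; a pooled
analyte-by-soil mode exists. Analytes beyond the covered suppression
are flagged in the output, not exempted. Covering −50% gives exactly 2.

`determine_iloq()` / `determine_mloq()` take the lowest solvent /
matrix-matched level with quantifier S/N ≥ 10 and qualifier S/N ≥ 3
(inclusive), MLOQ additionally requiring ion-ratio conformity. The base
MLOQ snaps to the calibration-level grid — it is defined as *the
concentration of a standard*, so interpolating between levels would
manufacture precision — and the corrected MLOQ multiplies by the global
factor (enforced ≥ 1). Quantification censors each record as
`quantified`, `below_mloq`, `above_linear_range` (re-dilution flag,
never extrapolated), `unconfirmed`, or `ilis_missing` (ILIS area zero
makes the PAR undefined; the sample is excluded and logged rather than
raising an error). Censored values contribute 0 to site sum
concentrations by default; MLOQ/2 substitution sits behind
`censored_value = "half_mloq"`. Replicates are quantified individually
and averaged at the reporting boundary.

## Surrogate-ILIS assignment

For analytes without a structure-identical ILIS,
`enumerate_candidates()` collects all same-polarity ILIS — restricted
to ±2 min retention time in positive mode, unrestricted in negative
mode where the pool is small. `candidate_recoveries()` evaluates each
pair by full re-quantification: candidate-specific calibration, then
spiked-minus-unspiked relative recoveries per evaluation soil (the
subtraction keeps native residues from biasing selection).
`score_and_select()` ranks by (1) soils inside the 70–120% band, (2)
dispersion $\sum_{\text{soils}} |r - 100|$, (3) $|\Delta RT|$, (4)
ILIS id — the last tie-break makes the assignment a total order, hence
deterministic. The hierarchy itself is the package's concretisation of
"ideally within 70–120% in all soils" and every stage of it is
reported in the audit table; assignments freeze into the method
configuration, and re-running against new soils yields a diff report
instead of silent reassignment.

## Figures of merit

* Relative recovery: $100\,(c_{\text{spiked}} -
  c_{\text{unspiked}})/c_{\text{spike level}}$ on ILIS-corrected
  concentrations. Because a pre-extraction-spiked ILIS shares the
  analyte's losses, relative recoveries center on 100% even when the
  extraction recovers less — which is precisely why the ILIS is spiked
  before extraction.
* Absolute recovery: blank-subtracted raw quantifier response of a
  pre-extraction spike over a post-extraction spike; this is the
  extraction efficiency itself.
* Precision: RSD = 100·sd/mean with the sample (n−1) standard
  deviation throughout (the divisor is a documented choice), computed
  on raw replicates (instrumental, intra-day), day means (inter-day,
  ≥3 days) or operator means (inter-person, ≥2 operators).
* Trueness versus an aged reference soil: per-analyte deviation from
  target plus the fraction beyond ±20%; strong negative deviations are
  expected for degradation-prone compounds and are findings, not
  errors.
* Proficiency z-scores: $z = (x_{\text{lab}} -
  \mathrm{median}(peers)) / (1.4826\,\mathrm{MAD}(peers))$, the robust
  median/MAD simplification of consensus-based scoring; panels with
  fewer than 8 peers are flagged because very small panels call for
  dedicated small-n procedures, which are out of scope.

## The synthetic batch generator

`simulate_batch()` exists so that every stage above is testable with
known truth. Its mechanism, per sample and species:

* matrix effect $\mathrm{ME}(i, s) = \beta\,C_{\text{org}}(s) +
  \sigma_{\mathrm{ME}} G_s(rt_i)$, with $\beta = -8$%/%C_org (so soils
  spanning 1–5% organic carbon reproduce median suppressions from
  roughly −8% to −40% against solvent, matching the monotone
  suppression-with-complexity trend such methods report),
  $\sigma_{\mathrm{ME}} = 10$ percentage points, and $G_s$ a standard
  Gaussian field over retention time with correlation
  $\exp(-|\Delta rt|/1\,\mathrm{min})$, drawn per soil extract. The
  solvent pseudo-matrix has exactly zero matrix effect.
* extraction recovery $0.95 + 0.05\,H_j(rt_i)$ per sample $j$, with
  $H_j$ an independent field with the same kernel — a
  structure-identical ILIS copies its analyte's value exactly
  (correlation 1), any other ILIS decorrelates with retention-time
  distance. This shared-shock structure is what makes surrogate
  selection by retention time meaningful.
* peak areas: expected response (area per ng/mL, lognormal across
  species, median ≈ 2000) times multiplicative lognormal noise with
  total CV 3%, split evenly in variance between a per-injection
  common-mode factor and a species residual. The split reflects how
  injection-volume and source fluctuations cancel in a peak-area
  ratio; it also makes the intra-day RSD of ILIS-corrected
  concentrations ≈ the nominal 3% rather than $\sqrt 2 \times$ it.
  Qualifier areas are the realised quantifier area times a per-species
  qualifier fraction (mean 0.4, sd 0.15, clipped to 0.05–0.95) times
  an independent 3% lognormal factor.
* S/N = area / noise floor, with the per-species floor at 0.2% of the
  response slope (lognormal spread 0.5), placing median ILOQs near
  0.025 ng/mL and base MLOQs at the lowest calibration levels —
  the sensitivity regime of a modern triple-quadrupole residue method.
* retention times jitter with sd 0.01 min; aged reference soils carry
  per-analyte loss fractions applied to a 10 ng/g spike
  (`make_reference_aged()`).

The fields are realised on a fixed 0.1-min grid as a stationary AR(1)
process (exact exponential kernel on the grid) and every draw is keyed
by a hash of the master seed and a stream label (species id, soil id,
sample id). A fixed seed therefore reproduces a batch bit for bit, and
draws attached to one identifier do not move when unrelated identifiers
are added.

What the generator does **not** emulate — and hence what passing tests
do not demonstrate about real data: chromatographic peak shapes and
integration errors, interferences and signal overlap, carryover,
drift across an injection sequence, calibration nonlinearity at the
range edges, heteroscedasticity beyond the multiplicative model, and
aging kinetics (loss fractions are free parameters, not kinetic
predictions). Conclusions from synthetic runs are about the *pipeline's
arithmetic and decision rules*, not about any instrument.

## Verification study sizes

The shipped tests and the acceptance script use, as the package's own
choices: a noise-free 146-analyte batch for exactness checks
(back-calculation within $10^{-9}$ relative; fits equal an independent
normal-equations solver within $10^{-10}$); one seeded stochastic
146-analyte batch (12-level duplicate calibration, solvent series,
five-soil matrix-effect experiment, quadruplicate spiked/unspiked
preparations in three soils) for the figure-of-merit bands; and a
200-run repeated-simulation study for surrogate selection. That study
places each analyte 0.05–0.15 min from one of six negative-mode ILIS
spaced ~1.6 min apart and evaluates twelve matrices spanning 1–5%
organic carbon: with the exponential kernel the deviation scale grows
like $\sqrt{\Delta rt}$, so a study with few matrices or with
candidates at comparable distances has essentially no power to resolve
the retention-time ordering — the near-coelution geometry mirrors the
regime real surrogate selections end up in (selected pairs typically
co-elute within ~0.1 min), and twelve matrices give the dispersion
ranking enough draws to be stable.

## Known limitations

Quantification is strictly linear (no quadratic fallback); above-range
samples are flagged for re-dilution, not extrapolated. Left-censored
statistics beyond zero/MLOQ-half substitution (Kaplan–Meier, ROS) are
out of scope, as are identification-point schemes for more than two
transitions, full consensus-algorithm proficiency scoring, and any
vendor-file or chromatogram handling.
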