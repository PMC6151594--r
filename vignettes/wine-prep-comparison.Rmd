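---
title: "Comparing sample-preparation methods in simulated ICP-MS wine profiling"
author: "vinelements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing sample-preparation methods in simulated ICP-MS wine profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Trace-element profiles of wine are used for authenticity and origin studies
and for monitoring toxic elements, but the profile a laboratory reports
depends on how the wine was prepared before it reached the ICP-MS. Four
treatments are in common use: direct dilution with dilute nitric acid (DD),
filtration through a 0.45 µm membrane before (FA) or after (AF)
acidification, and closed-vessel microwave-assisted acid digestion (MW).
Each treatment perturbs the measurement differently — digestion reagents add
contamination, filters retain organically complexed analytes, and the
methods differ in replicate precision. `vinelements` implements the complete
analytical and statistical workflow for studying these perturbations, driven
by a synthetic instrument-data generator, so every stage is testable without
access to instrument data.

The package is organised as three pipeline stages over a single long-format
CSV interchange:

1. `run_simulate()` — generate a full analytical batch (calibration series,
   calibration blanks, method blanks, QC standards, wines and spiked
   aliquots for 43 isotope channels);
2. `run_quantify()` — external calibration, detection limits, censoring,
   quality control, spike recovery, isotope-dilution copper;
3. `run_compare()` — MANOVA gate, per-isotope ANOVA with Tukey letter
   displays, blank-compromise exclusion, correlation-matrix PCA and
   precision summaries.

## The forward model

The generator is mole-resolved. For one measured solution, the content of a
channel (element $e$, mass $m$) collects contributions from every copper or
lead source in the solution in proportion to that source's isotopic
abundance at $m$:

$$A_{e,m} \;=\; W_e \Big( \tfrac{c_{\mathrm{nat}}}{W_e}\, b_m \,\rho_{e,m}
  \;+\; \tfrac{c_{\mathrm{spk}}}{W_{\mathrm{spk}}}\, a_m \Big) \;+\;
  \kappa_{e,m},$$

where $c_{\mathrm{nat}}$ is the wine-derived element concentration at the
instrument (truth divided by the preparation dilution factor), $b_m$ and
$a_m$ are the natural and spike mole fractions at mass $m$, $W$ are atomic
weights, $\rho \in (0,1]$ is the filtration retention applied to the
wine-derived analyte, and $\kappa$ is additive reagent contamination.
Elements that receive no enriched spike are carried as a single isotope
bucket ($b_m = 1$), which is exact for external calibration because the
abundance factor cancels against natural-abundance standards. The response
is

$$\text{response} = s_{e,m}\, A_{e,m}\, \mu\, \delta_i\, \eta + \beta,$$

with sensitivity $s$, matrix factor $\mu$ (1 by default: samples and
standards are matrix-matched), a bounded multiplicative random-walk drift
$\delta_i$ over acquisition order shared with the internal-standard
channels, unit-mean lognormal noise $\eta$, and background counts $\beta$
with additive Gaussian spread (which is what blank-based detection limits
measure). Sensitivities are equal across the isotopes of one element, so
the 63Cu:65Cu response ratio is an atom ratio — the simulated instrument has
no mass bias, matching the quantitation model, which carries a mass-bias
hook that defaults to the identity.

### Noise structure

Replicate noise of prepared solutions is multiplicative lognormal at the
method's CV — concentrations are positive and precision is reported as
percent RSD. The log-variance is split between a **common-mode** component
shared by all analyte channels of one solution (preparation and transport
fluctuations; default share 0.8) and a **channel-specific** remainder.
Internal-standard normalization cancels drift but not the common-mode
component (the IS is fed separately into the spray chamber); an isotope
*ratio* of two channels of the same element cancels both. This split is what
decides whether isotope dilution is more precise than external calibration:
with the common-mode share at 0.95 ("drift-dominant" conditions) isotope
dilution is clearly more precise, while at the default 0.8 the two are
comparable, because the mixing-equation inversion amplifies ratio noise by a
factor $S(R) = R\,[a_{65}/(Ra_{65}-a_{63}) + b_{65}/(b_{63}-Rb_{65})]
\approx 2$ at typical wine copper levels.

### Default study conditions

* **Design**: 4 wines (C, PN, S, T) × 4 methods × 3 replicates, triplicate
  method blanks per method, spiked counterparts of every wine and blank,
  six-point calibrations 0–500 µg/L per matrix group (4 % ethanol / 5 %
  HNO~3~ for the direct methods; 5 % HNO~3~ for MW), a separate six-point
  enriched-material calibration, a 10 µg/L QC standard every 15 solutions,
  and continuing calibration blanks: 6 per run in two runs for the direct
  group, 8 in one run for MW.
* **Dilution factors**: 3 for DD/FA/AF ("diluted 1:3" read as one part
  sample in three parts total, which maps 12–15 % ethanol wine onto the 4 %
  ethanol calibration matrix) and 10 for MW (2 mL sample + 2 mL acid,
  digest diluted 1:5). Both are configurable for laboratories that read
  1:3 as 1 + 3.
* **Noise CVs**: MW 0.295; DD 0.13, FA 0.155, AF 0.18 (the direct methods'
  reported 13–18 % band).
* **Contamination**: per-channel lognormal draws (CV 0.5, emulating
  replicate-to-replicate reagent variability) around means taken from a
  reference blank profile in which MW is by far the dirtiest method
  (e.g. Mn above 20 µg/L). The profile is tabulated on the *reported*
  concentration scale, so the at-instrument default is the tabulated value
  divided by the method's dilution factor — then a quantified,
  dilution-corrected method blank reproduces the profile.
* **Filtration retention**: 0.85–0.92 on the eleven channels lowered by
  both filtration treatments (⁷Li, ⁵⁹Co, ⁶³Cu/⁶⁵Cu, ⁸⁵Rb, ⁸⁸Sr, ⁹³Nb,
  ¹³³Cs, ¹⁸²W, ²⁰⁵Tl, ²⁰⁶Pb/²⁰⁸Pb), with an additional 0.90 in AF only for
  the seven channels where AF reads below FA. Retention applies to the
  wine-derived analyte; the freshly added ionic spike is assumed not to be
  complexed to wine colloids and passes the filter.
* **Truth table**: per-(wine, element) true concentrations drawn
  log-uniformly within element ranges spanning ~3 ng/L (rare-earth
  elements) to above 1 mg/L (Mn, Rb), so the four wines carry distinct,
  separable profiles.
* **Spikes**: one gravimetric spike mix (0.1 g into a 10 g aliquot)
  delivering 100 µg/L enriched Cu and 5 µg/L enriched Pb in the spiked
  sample. The isotopic abundance vectors (a₆₅ = 0.99 for Cu, a₂₀₆ = 0.99
  for Pb) are *synthetic placeholders* for a highly enriched material, not
  certificate values; real analyses must substitute the manufacturer's
  certified abundances in the configuration.
* **Instrument**: flat sensitivities (1000 counts per µg/L), 1 % baseline
  repeatability for solutions that undergo no preparation (standards, QC,
  calibration blanks), background 5 ± 1 counts, drift steps of 1 % clamped
  to [0.8, 1.2]. The 1 % baseline matters: with unweighted least squares
  over 0–500 µg/L, multiplicative noise at the high-leverage standards
  propagates into the intercept roughly as ±(CV × 100 µg/L), and a 3 %
  baseline would produce spurious QC failures at the 10 µg/L check level.

## Quantitation conventions

* **Calibration** is unweighted ordinary least squares of the
  internal-standard-normalized response on the gravimetric concentration,
  per channel, matrix group and calibration material. Internal standards
  are assigned by nearest mass among ⁶Li, ⁴⁵Sc, ⁷²Ge, ⁸⁹Y, ¹¹⁵In, ¹⁵⁹Tb,
  ²⁰⁹Bi — a convention (the pairing is rarely reported), stored in the
  configuration and freely overridable. Both Cu channels share one internal
  standard by construction, so the 63/65 ratio is IS-free.
* **Detection limits** use the blank-SD convention LOD = t × SD with t the
  *one-tailed 99 %* Student quantile at n − 1 degrees of freedom — the
  convention that reproduces the standard multipliers 3.365 (n = 6) and
  2.998 (n = 8); the confidence level is configurable. LOQ = 10 × SD.
  Direct-method limits are averaged over two analytical runs. Limits are
  tabulated at solution (instrument) scale; for censoring they are
  multiplied by the method's dilution factor to sit on the reported
  concentration scale.
* **Censoring** replaces every value below its detection limit by half the
  limit and flags it. The flag guards idempotence: the substituted LOD/2 is
  itself below the LOD but is never re-censored.
* **QC**: the repeated 10 µg/L standard must be accurate within 20 % and
  precise below 20 % RSD per channel; failures flag the run (and stop it
  under `strict = TRUE`).
* **Spike recovery** is 100 × (spiked − mean unspiked)/level. Spiked
  aliquots are quantified on the *enriched-material* calibration of the
  spike channel, which makes the natural contribution cancel exactly in
  the difference — a lossless preparation recovers 100 %. Quantifying an
  enriched spike against a natural-abundance curve would misread the
  recovery by the abundance ratio (≈3× for ⁶⁵Cu).
* **Isotope dilution** inverts the two-source mixing balance
  $$c = c_{\mathrm{spk}}\,\frac{m_{\mathrm{spk}}}{m_{\mathrm{spl}}}\,
     \frac{W_{\mathrm{nat}}}{W_{\mathrm{spk}}}\,
     \frac{R\,a_{65}-a_{63}}{b_{63}-R\,b_{65}},$$
  with R the measured 63/65 response ratio and natural abundances
  b₆₃ = 0.6915, b₆₅ = 0.3085. Atomic weights are derived from the abundance
  vectors and exact isotope masses, so the inversion is the exact inverse
  of the mole balance. R at the natural ratio is a singularity (error); R
  outside the interval between the pure-spike and natural ratios is
  inconsistent with two-source mixing (warning). Because spike and analyte
  share every preparation step, a proportional, non-fractionating loss
  cancels in the ratio. No mass-bias correction is applied, by design.

## Statistical stage

* **MANOVA gate**: Pillai trace (a robust default) of the method effect,
  with sample, replicate and method as main effects. The full 43-channel
  test on the 48-observation design is singular (39 residual degrees of
  freedom), so `manova_method_effect()` stops with instructions and the
  pipeline gate projects the standardized replicate matrix onto leading
  principal components (95 % of variance, capped below the residual
  degrees of freedom) before testing.
* **Per-isotope ANOVA** fits the main effects sample, replicate and method
  with no interactions on the balanced design (unbalanced input is an
  error; constant channels are flagged degenerate). On balanced designs the
  sequential sums of squares decompose exactly and match a brute-force
  group-mean computation, which the tests exploit as an oracle.
* **Tukey letters**: groups differ when their means differ by more than
  HSD = q(0.95, k, df) √(MSE/n). With equal group sizes the
  not-different relation on sorted means is an interval relation, so the
  compact letter display is exactly the set of maximal runs of mutually
  not-different groups — two groups share a letter *iff* they are not
  significantly different, verified against exhaustive pairwise
  comparison.
* **Blank-compromise exclusion** re-runs the ANOVA with method blanks as an
  extra sample level and excludes channels with (i) no significant sample
  effect or (ii) a method whose blank mean reaches the wine mean. Running
  the blanks as a fifth level (rather than a separate test) is the default
  reading of an ambiguous procedure; both inputs are available to the user.
* **PCA** standardizes channels to zero mean and unit variance (the
  correlation-matrix convention, required when concentrations span five
  orders of magnitude), drops zero-variance (fully censored) channels with
  a warning, and fixes each component's sign so its largest-magnitude
  loading is positive. Scores are invariant to per-column affine
  rescaling. The PCA runs on sample means (wine × method), not replicates.
* **Precision summaries** average per-(wine, method, channel) replicate
  RSDs over channels detected in all replicates. Note that the n = 3
  sample SD is attenuated (E[s] = c₄σ, c₄(3) = 0.886), so a method
  simulated at CV 0.295 yields a mean replicate RSD near 25 %, not 29.5 %;
  the tests assert the c₄-corrected value.
* No multiple-testing correction is applied across the per-isotope ANOVAs
  (each channel is reported at p ≤ 0.05); a Benjamini–Hochberg adjustment
  can be applied to the exported p values by the user.

## Monte Carlo problem sizes

The statistical-calibration studies run on the concentration-level
generative model (`simulate_concentrations()`), which applies the effect
and noise model directly to the truth table — the instrument/calibration
layer is exact (the noise-free round trip reproduces the truth to below
10⁻⁹ relative) and is exercised separately, so bypassing it in the Monte
Carlo loops changes nothing but the cost. The package's chosen study sizes
are: 1000 random parameter draws for the isotope-dilution inversion check,
200 batches for the filtration-retention recovery (ratio 0.80 at CV 0.15,
n = 3), 500 null batches for the ANOVA type-I rate, and 200 batches for
MANOVA power under the default microwave contamination.

## What the generator does and does not emulate

Emulated: method-specific contamination with replicate variability,
filtration losses, method-specific precision, acquisition drift with
internal-standard cancellation, matrix-matched calibration per group,
gravimetric spiking, blank-limited detection, and censoring.

Not emulated: spectral (polyatomic) interferences and collision-cell
kinetics — channel and cell-gas mode choices are carried as metadata only;
instrumental mass bias (deliberately, matching the quantitation model);
inter-element sensitivity differences (flat 1000 counts/µg/L);
signal-dependent (shot-noise) precision — the per-method CV is
homoscedastic across channels, so simulated spike-recovery RSDs inherit
the full method CV rather than the smaller high-signal precision a real
instrument shows; and real wines' concentrations, which are represented by
random but realistic truth tables. Passing tests therefore demonstrate the
correctness and statistical calibration of the *workflow*, not agreement
with any particular wine.

## Reproducibility

Every simulation call requires an explicit seed; a configuration without
one is refused. Stage outputs carry a manifest with the seed, the MD5 hash
of the canonical configuration JSON and the record counts, and rerunning a
stage from the same configuration is byte-identical. Record counts are
logged at stage boundaries so that "no silent drops" is auditable.
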