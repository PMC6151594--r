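# vinelements

Simulated ICP-MS elemental profiling of wine, and the statistics for
comparing sample-preparation methods.

## What problem this addresses

Elemental profiles measured in wine by inductively coupled plasma mass
spectrometry (ICP-MS) depend on how the wine was prepared: direct dilution
(DD), filtration before or after acidification (FA, AF), and
microwave-assisted acid digestion (MW) each perturb the result through
reagent contamination, retention of organically complexed analytes on the
filter, and method-specific replicate precision. `vinelements` implements
the full analytical and statistical workflow for studying these
perturbations — driven by a synthetic instrument-batch generator, so every
stage is testable end to end. It is aimed at analytical chemists and method
developers who want a reproducible, fully specified model of this class of
experiment: 43 isotope channels, 4 wines × 4 preparation methods × 3
replicates, six-point matrix-matched calibrations, blank-based detection
limits, and spiked aliquots for recovery and isotope-dilution quantitation.

## The core models

**External calibration.** Channel responses are normalized to a
continuously aspirated internal standard and mapped to concentration by an
unweighted least-squares line per channel and matrix group; reported
concentrations are dilution-corrected. Detection limits follow the blank-SD
convention LOD = t × SD with t the one-tailed 99 % Student quantile at
n − 1 degrees of freedom (3.365 for n = 6 blanks, 2.998 for n = 8), and
values below the LOD are replaced by LOD/2 for statistics.

**Isotope dilution.** Copper in spiked samples is quantified from the
measured ⁶³Cu:⁶⁵Cu response ratio R by inverting the two-source mixing
balance

    [Cu] = c_spike (m_spike/m_sample) (W_nat/W_spike) (R a65 − a63)/(b63 − R b65)

with natural abundances b63 = 0.6915, b65 = 0.3085 and spike abundances
a63, a65 from the certificate. Because spike and analyte share every
preparation step, proportional losses cancel in the ratio.

**Method comparison.** A Pillai-trace MANOVA gate (on leading
principal-component scores when the channel count exceeds the residual
degrees of freedom), per-isotope main-effects ANOVA (sample, replicate,
method) with Tukey HSD compact letter displays, exclusion of
blank-compromised channels, correlation-matrix PCA of sample-mean
profiles, and per-method replicate-RSD summaries.

## Worked example

```r
library(vinelements)

cfg <- default_config(seed = 42)           # seed is mandatory
sim <- run_simulate(cfg, "batch.csv")
#> simulate: 172 solutions -> 7396 records -> batch.csv

q <- run_quantify(sim$records, cfg)
#> quantify: 7396 records -> 5160 quantified (1516 censored), QC passed

cmp <- run_compare(q$quant, cfg)
#> compare: 2064 observations, 17 channels excluded, 28 with a significant method effect
```

The detection-limit table is per matrix group at solution scale; for the
direct methods it averages two analytical runs of six calibration blanks
(t = 3.365):

```r
head(q$lod[q$lod$method == "direct", ], 3)
#>  method element mass n_blanks n_runs t_value         lod         loq
#>  direct      Li    7        6      2 3.36493 0.004370270 0.012987700
#>  direct      Al   27        6      2 3.36493 0.003472934 0.010320970
#>  direct      Ti   47        6      2 3.36493 0.002727668 0.008106165
```

Replicate precision by method shows microwave digestion as the least
precise treatment (simulated at CV 0.295 against 0.13–0.18 for the direct
methods; the n = 3 sample RSD is attenuated by the usual c₄ factor):

```r
cmp$rsd
#>  method mean_rsd n_groups
#>      AF 14.81888      129
#>      DD 11.10480      130
#>      FA 13.64810      128
#>      MW 27.46893      119
```

The preparation-method effect is confirmed multivariately
(`cmp$manova`: Pillai = 1.139, p = 1.2e-06), 28 of 43 channels show a
significant method effect in this run, and mean spike recoveries across the
wines are 108 % (⁶⁵Cu at 100 µg/L) and 103 % (²⁰⁶Pb at 5 µg/L). Per-channel
method means carry Tukey letters (groups sharing a letter are not
significantly different at α = 0.05):

```r
head(subset(cmp$letters, element == "Li"), 4)
#>  element mass method     mean letter
#>       Li    7     AF 27.30578      a
#>       Li    7     DD 30.00350      a
#>       Li    7     FA 27.86654      a
#>       Li    7     MW 31.64475      a
```

A thin command-line front end over the same three stages is installed at
`inst/cli/vinelements.R` (subcommands `simulate`, `quantify`, `compare`,
each taking a JSON configuration written by `write_config()`).

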