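---
title: "Methods: ammonia-oxidizer growth, stability and nitrification apportionment"
author: "nitrostab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ammonia-oxidizer growth, stability and nitrification apportionment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrostab)
```

## The system and the questions

Soil nitrification begins with ammonia oxidation, carried out by three
guilds: ammonia-oxidizing archaea (AOA), canonical ammonia-oxidizing
bacteria (AOB) and complete ammonia oxidizers (comammox *Nitrospira*). Soil
pH partitions these guilds into niches, so a pH perturbation — for example
the acidification that follows intensive ammonium fertilization when
tropical forest is converted to oil palm plantation — can reorganize both
the community and the process rate. A microcosm experiment addressing this
incubates each soil at its native pH and at a modified pH (acidified or
limed), under either ¹²CO₂ or ¹³CO₂ headspace, with destructive triplicate
sampling over a 30-day incubation. The measurements are: NH₄⁺, NOₓ⁻ and pH
(colorimetric chemistry), per-guild *amoA* gene copies (qPCR), and
per-fraction *amoA* copies across a CsCl buoyant-density gradient (DNA-SIP)
at the end of incubation.

`nitrostab` implements the full downstream analysis of such an experiment,
plus a synthetic data generator that emulates the design with known ground
truth, so that every estimator in the package can be validated by parameter
recovery rather than by eye.

## Analysis model

### Net nitrification

The net nitrification rate of a soil × pH condition is the increase in
NOₓ⁻ over the incubation, `delta = mean(NOx_30) - mean(NOx_0)`, with a
Student's *t* test against the null of no change
(`net_nox_production()`). Replicate-level rates feed a two-way soil ×
condition ANOVA with Tukey HSD compact-letter groupings
(`anova_with_posthoc()`; letters via **multcomp**).

### Growth: qPCR and DNA-SIP

Growth of a guild is estimated two ways, deliberately kept on the same
footing (`growth_estimate` objects) so that everything downstream is
method-agnostic:

* **qPCR**: final minus initial mean abundance. Growth is *detected* only
  when the increase is positive **and** a one-sided two-sample *t* test
  (pooled df, reconstructed from the summary statistics) rejects at
  `alpha`; otherwise the result is reported as "n.d.". A decline is by
  definition not growth.
* **DNA-SIP**: growing cells assimilate ¹³C, increasing the buoyant density
  of their DNA. Each gradient is first normalized
  (`normalize_profile()`): relative abundance of fraction *i* is its copy
  count divided by the summed counts over the quantified fractions, so a
  profile is a probability distribution over fractions (this invariant is
  asserted on construction). Labelling is called
  (`detect_labeling()`) when the abundance-weighted mean density (WMD) of
  the ¹³C replicates exceeds that of the ¹²C replicates by at least
  `delta_min` **and** a one-sided two-sample *t* test on replicate WMDs
  rejects at `alpha`. The labelled population is then quantified
  (`labeled_abundance()`) as the total qPCR abundance times the ¹³C
  profile's mass in the *heavy window* (density ≥ `heavy_threshold`).

The two-part labelling rule exists because "distinct peaks" is a
qualitative criterion: the *t* test alone would call minute but consistent
shifts, and the effect-size floor alone would call large noisy ones. The
combination is conservative — its false-positive rate on unlabelled guilds
sits below the nominal `alpha` (the *t*-test component alone is calibrated
to `alpha`; both rates are recomputed by `scripts/acceptance.R`).

### Stability

The response of a guild to the pH perturbation is summarized by the
stability index

\[ S = 100 \times \frac{\bar M - \bar N}{\bar N}, \]

where \(\bar M\) and \(\bar N\) are mean day-30 abundances in the modified
and native soil. \(S = 0\) is the neutral point (maximal stability);
\(S < 0\) indicates undercompensation, \(S > 0\) overcompensation, and
\(S \ge -100\) whenever abundances are non-negative. Because modified and
native microcosms are independent, per-replicate values are formed by
referencing each modified replicate to the native mean,
\(S_i = 100 (M_i - \bar N)/\bar N\); their mean equals \(S\) and their
spread feeds the independent *t* tests that compare guild stabilities
within a soil (`compare_stability()`). This replicate convention is a
package design choice: with independent triplicates no pairing exists, and
referencing the native mean keeps the index's point estimate unchanged
while attributing all replicate-level spread to the perturbed community.

### Apportionment

A growing population's putative contribution to nitrification is an upper
bound obtained by holding every grown cell at the highest recorded maximum
cell-specific activity for the whole incubation:

```
cells  = growth / copies_per_cell
ug N   = cells x activity [fmol NH3 cell^-1 h^-1] x hours x 1.4e-8
```

(1 fmol NH₃ = 10⁻¹⁵ mol × 14 g mol⁻¹ = 1.4 × 10⁻⁸ µg N). Defaults are 720 h
(30 days), one *amoA* copy per cell (AOB genomes often carry 2–3; the
parameter is exposed), and the reference activities 2.6 / 23 / 2.6 fmol NH₃
cell⁻¹ h⁻¹ for AOA / AOB / comammox (`default_cell_activities()`). The
comammox constant is derived rather than measured directly
(`derive_cell_activity()`): a V_max of 14.8 µmol NH₃ mg⁻¹ protein h⁻¹,
5.7 g wet weight per g protein and 10¹² cells per g wet weight give
2.5965 ≈ 2.6 fmol cell⁻¹ h⁻¹. Holding the end-of-incubation growing
population at maximum activity for the full duration is intentionally
generous; a `trapezoidal` integration option (half the exposure) exists for
users who prefer a time-averaged population.

`apportion()` compares the summed contributions with the measured net NOₓ⁻
production: `unaccounted = max(0, measured - sum)`. When the theoretical sum
exceeds the measurement the breakdown is flagged `overexplained` and the
contributions are reported as-is — they are upper bounds, not a partition,
so rescaling them would misrepresent the arithmetic. A positive unaccounted
residual means the measured nitrification cannot be explained even at
maximum recorded activities: other oxidizers, or higher-than-recorded cell
activity.

`scale_area_emission()` is the small utility for area-scaling a per-hectare
emission rate to a global total (kg N ha⁻¹ yr⁻¹ × ha × 10⁻⁹ = Tg N yr⁻¹).

## The simulator

`simulate_dynamics()` advances a soil microcosm in daily steps:

1. guilds with positive growth rate multiply by `exp(rate)` while NH₄⁺
   exceeds a limitation threshold (default 1 µg N g⁻¹); declining guilds
   always decline. Growth adds `autotroph_fraction` of the new copies to
   the guild's ¹³C-labelled pool;
2. the community oxidizes `min(NH4 + mineralization, potential)` µg N,
   where the potential is the summed `cells × activity × 24 h` of all
   guilds; oxidized N is attributed to guilds proportionally to their
   potential (the ground-truth contribution);
3. `NH4 += mineralization − oxidation`, `NOx += oxidation`, and pH falls by
   `oxidation / buffer_capacity`.

Daily discrete steps (not ODEs) are adequate at a 30-day horizon and make
every worked example checkable by hand; the hard NH₄⁺ threshold stands in
for Monod kinetics because the emulated behaviour (growth stalls when
ammonium runs low) is qualitative. The scheme conserves mass exactly:
`Δ(NH4 + NOx) = mineralization` at every step, and the per-guild oxidation
shares sum to the total NOₓ⁻ production — both are asserted in the test
suite.

Measurements (`simulate_measurements()`) perturb every true value with
independent, unit-mean multiplicative lognormal noise: `qpcr_cv` (default
0.2) for abundances, `chem_cv` (default 0.1) for NH₄⁺/NOₓ⁻, and a separate
small `ph_cv` (default 0.01) for pH — pH electrodes are far more precise
than colorimetric N assays, so giving pH the chemistry CV would inject
±0.6-unit errors no lab would accept. Abundances can therefore never go
negative. The design is the study layout: triplicate day-0 microcosms
(isotope `"none"`, sampled before CO₂ amendment) and triplicates per
isotope at days 15 and 30.

Gradients (`simulate_gradient()`) place a guild's DNA at
`1.66 + 0.098 × GC` g ml⁻¹ (the standard linear GC–density relation), shift
the labelled pool by up to `max_label_shift = 0.036` g ml⁻¹, spread each
pool as a Gaussian with σ = 0.008 g ml⁻¹, and integrate over 15 fraction
bins spanning 1.66–1.76 g ml⁻¹ (fraction 1 = heaviest; densities decrease
with index; bins renormalized so pre-noise copies sum exactly to the
input abundance). Fractions 2–14 are "quantified", mirroring the common
practice of discarding the extreme fractions. All density-model constants
are configurable defaults of this standard relation. Example-guild GC
contents (0.41 / 0.53 / 0.59 for AOA / AOB / comammox) follow typical
genome GC of the guilds.

`example_scenarios()` parameterizes five soils along a land-use gradient —
two forest soils, a riparian soil and two oil palm soils — with the
qualitative behaviour expected from pH niche specialization: acidification
depresses AOB strongly and AOA mildly, liming boosts both (AOB most), and
comammox responds weakly. Realized per-cell activities are set far below
pure-culture maxima, as in soil, which is also why apportionment at maximum
activities typically overexplains. `closure_scenarios()` is the idealized
variant for budget-closure checks: every guild fully autotrophic and
growing at 0.1 d⁻¹ with ample ammonium, with standardized true activities
(`closure_activities()`), so that a noise-free run analysed at the true
rates must leave zero unaccounted NOₓ⁻ in every soil.

### What the simulator does and does not emulate

It emulates: the factorial design and replication; ammonium limitation;
pH drift from proton release during nitrification; unbiased lognormal
measurement error; GC- and labelling-driven buoyant density structure with
partial labelling (mixtures of labelled and unlabelled DNA). It does not
emulate: NH₃/NH₄⁺ speciation chemistry, N₂O fluxes, within-guild
(e.g. comammox clade A/B) substructure, qPCR inhibition or efficiency bias,
density measurement error on fractions, or gradient-to-gradient density
calibration drift. Passing recovery tests therefore demonstrates that the
estimators are correct under the stated noise model, not that real soils
satisfy that model.

## Numerical choices and degenerate inputs

* **Zero-variance inference.** Noise-free data produce zero standard
  errors; t statistics are then ±∞ with p ∈ {0, 1} rather than NaN, so
  noise-free recovery runs behave sensibly.
* **All-zero gradients** yield an explicit no-signal profile, and labelling
  with a no-signal side is a `"no_call"`, distinct from `"unlabeled"` —
  absence of amplification is not evidence of no growth.
* **Clamps.** `unaccounted` is clamped at 0 (with an `overexplained` flag);
  labelled proportions above 100% are clipped with a warning; negative or
  undetected growth contributes 0 µg N.
* **Heavy-window geometry.** With σ = 0.008 g ml⁻¹, a 0.036 g ml⁻¹ label
  shift and quantified fractions 2–14, noise-free recovery of the labelled
  fraction is bin-quantization-limited (≤ 3 percentage points) when both
  density modes lie inside the quantified window and the window threshold
  sits between the two peaks. With the generic default threshold
  (1.725 g ml⁻¹) and arbitrary GC, part of a high-GC labelled peak spills
  into unquantified fraction 1 (or the threshold clips a low-GC labelled
  peak) and the error can reach several points; the Monte-Carlo recovery
  checks at default settings are therefore held to ±10 points. In practice
  one should place the heavy window relative to the observed unlabelled
  peak, and the ¹²C-background subtraction option (`subtract_12C`, off by
  default to mirror the plain heavy-fraction computation) exists because
  unlabelled heavy-tail mass otherwise inflates estimates of weakly
  labelled, high-GC guilds.
* **No multiple-testing correction by default**; the workflow mirrors the
  classical per-test convention, and `p.adjust`-style correction can be
  applied by the user on the returned tables.

## Problem sizes used in validation

Calibration experiments in the test suite and acceptance script use 200
seeded Monte-Carlo replicates per rate (power and false-positive rate of
labelling detection, qPCR growth detection, labelled-fraction recovery),
triplicate microcosms at default noise, and one full noise-free closure run
over all five soils × two conditions × both growth methods. These sizes
give binomial standard errors below 2 percentage points on estimated rates
while keeping the whole suite fast.

## Known limitations

* The stability index compares means of independent groups; its
  per-replicate spread convention (modified replicates against the native
  mean) understates native-side uncertainty in the guild-comparison tests.
* Heavy-window quantification is biased low when labelled mass leaves the
  quantified fraction range, and biased high for high-GC guilds whose
  unlabelled tail enters the window (see above).
* Contributions are upper bounds under the maximum-activity convention;
  `overexplained` breakdowns carry no information about the true split
  among guilds.
* The simulator's lognormal noise is unbiased and independent across
  replicates and fractions; real qPCR error is often correlated within
  plates and gradients.
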