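# nitrostab

Growth, stability and nitrification apportionment of soil ammonia oxidizers
from DNA-SIP microcosm experiments.

## The problem

Ammonia oxidation, the first and rate-limiting step of nitrification, is
carried out in soil by three guilds — ammonia-oxidizing archaea (AOA),
ammonia-oxidizing bacteria (AOB) and complete ammonia oxidizers (comammox
*Nitrospira*) — whose niches are strongly structured by pH. When land use
shifts soil pH (e.g. acidification of tropical soils under oil palm
cultivation), the guilds respond differently, with consequences for the
nitrification rate and for N₂O emissions. The standard experiment is a
pH-perturbation microcosm study: each soil incubated at native and modified
pH under ¹²CO₂ or ¹³CO₂, with chemistry (NH₄⁺, NOₓ⁻, pH), per-guild *amoA*
qPCR time series, and end-point DNA stable-isotope-probing (SIP) CsCl
density gradients.

`nitrostab` is the analysis pipeline for that design, for microbial
ecologists working with SIP/qPCR microcosm data:

* **SIP gradients** — per-fraction counts → normalized density profiles
  (relative abundance per fraction, summing to 1), ¹³C-labelling calls from
  abundance-weighted mean density (WMD) shifts (effect-size floor +
  one-sided *t* test), and heavy-window quantification of the labelled
  (growing) population.
* **Rates and growth** — net nitrification `ΔNOx = mean(NOx₃₀) − mean(NOx₀)`
  with *t* test vs no change; guild growth by qPCR (final − initial, with
  the "n.d." convention: growth must be a *significant increase*) and by
  SIP (labelled abundance), on a common footing.
* **Stability** — the ecosystem-function stability index
  `S = 100 × (M − N)/N` for modified (M) vs native (N) day-30 abundance:
  `S = 0` neutral, `S < 0` undercompensation, `S > 0` overcompensation,
  bounded below by −100; with independent *t* tests comparing guilds.
* **Apportionment** — putative per-guild NOₓ⁻ production
  `µg N = cells × activity × hours × 1.4×10⁻⁸` at the highest recorded
  cell-specific activities (2.6 / 23 / 2.6 fmol NH₃ cell⁻¹ h⁻¹ for
  AOA / AOB / comammox), the unaccounted residual
  `max(0, measured − Σ contributions)`, and derivation of per-cell
  activities from culture kinetics.
* **Synthetic microcosms** — a simulator of the whole design (daily
  NH₄⁺/NOₓ⁻/pH/abundance dynamics, lognormal measurement noise, two-component
  Gaussian density gradients) with ground truth, used to validate every
  estimator by parameter recovery.

See `vignettes/nitrostab-methods.Rmd` for the full model description,
defaults and limitations.

## Worked example

```r
library(nitrostab)

ds  <- generate_dataset(example_scenarios(), sim_config(seed = 42))
res <- run_pipeline(ds)

dplyr::filter(res$rates, soil_id %in% c("E", "OP7"))
#>   soil_id condition delta_nox    se     t    df           p significant
#> 1 E       native        22.1  0.943 20.2      7 0.000000180 TRUE
#> 2 E       modified       2.77 0.517  3.84     7 0.00635     TRUE
#> 3 OP7     native         1.66 0.546  2.98     7 0.0205      TRUE
#> 4 OP7     modified       6.50 0.470 10.1      7 0.0000204   TRUE
```

Forest soil E nitrifies fast at native pH (22.1 µg N g⁻¹ over 30 days) and
collapses under acidification (2.8); oil palm soil OP7 speeds up when limed
(1.7 → 6.5). The guild stabilities behind the E-soil collapse:

```r
dplyr::filter(res$stability, soil_id == "E")
#>   soil_id guild    stability compensation n
#> 1 E       AOA          -56.4 under        6
#> 2 E       AOB          -98.8 under        6
#> 3 E       comammox      15.9 over         6
```

AOB are nearly eliminated by acidification (−98.8%), AOA are partially
depressed, comammox is stable — the differential-stability pattern this
analysis is designed to expose. Labelling calls and the contribution
breakdown for limed OP7:

```r
dplyr::filter(res$labeling, soil_id == "OP7", condition == "modified")
#>   soil_id condition guild    call      delta_wmd        p labeled_abundance
#> 1 OP7     modified  AOA      labeled     0.0282  2.47e-05        3.93e8
#> 2 OP7     modified  AOB      labeled     0.0272  8.50e-07        1.47e6
#> 3 OP7     modified  comammox unlabeled   0.0048  8.74e-04        1.09e5

dplyr::filter(res$apportionment, soil_id == "OP7",
              condition == "modified", method == "sip")
#>   soil_id condition method component   nox_ug measured_nox overexplained
#> 1 OP7     modified  sip    AOA         10301.         6.50 TRUE
#> 2 OP7     modified  sip    AOB           341.         6.50 TRUE
#> 3 OP7     modified  sip    comammox        0          6.50 TRUE
#> 4 OP7     modified  sip    unaccounted     0          6.50 TRUE
```

AOA dominate the labelled community; at *maximum* recorded activities the
growing populations could have produced far more NOₓ⁻ than measured
(`overexplained`), so nothing is left unaccounted — contributions are upper
bounds, never rescaled. The two worked constants:

```r
derive_cell_activity(14.8, 5.7, 1e12)
#> <cell_activity> 2.6 fmol NH3 cell^-1 h^-1
round(scale_area_emission(1.2, 19e6), 2)   # kg N/ha/yr over 19 Mha, in Tg
#> 0.02
```

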