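Package: nitrostab
Title: Growth, Stability and Nitrification Apportionment of Soil Ammonia
    Oxidizers from DNA-SIP Microcosms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for pH-perturbation soil microcosm experiments
    on ammonia oxidizers (ammonia-oxidizing archaea, ammonia-oxidizing
    bacteria and comammox Nitrospira). Converts per-fraction amoA counts from
    CsCl buoyant-density gradients into normalized density profiles, detects
    13C labeling of each guild, and quantifies labeled (growing) populations;
    estimates growth from qPCR time series; computes net nitrification rates,
    an ecosystem-function stability index with compensation classification,
    and the classical t-test/ANOVA significance workflow; and apportions
    measured NOx production among guilds using cell-specific ammonia
    oxidation activities, with an unaccounted residual. Includes a synthetic
    microcosm and gradient simulator with known ground truth for recovery and
    calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    multcomp,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
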