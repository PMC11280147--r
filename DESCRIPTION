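Package: glennpvr
Title: Per-Lung Pulmonary Vascular Resistance Estimation for Glenn Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the pulmonary vascular resistance (PVR) of each lung in
    children with Glenn (bidirectional cavopulmonary) physiology from routine
    cardiac MRI flow and catheterization pressure data. Provides a 0D resistive
    lumped-parameter model of the Glenn circuit solved in closed form, a
    Nelder-Mead calibration of the two outlet resistances against clinical flow
    waveforms and mean superior vena cava pressure, a direct computed-PVR
    baseline (pressure gradient over branch flow), synthetic flow-waveform
    generation for parameter-recovery studies, and the method-agreement
    statistics (ICC(2,1), Bland-Altman, normality-gated paired tests) used to
    compare estimates. Ships a 16-patient reference cohort as package data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
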