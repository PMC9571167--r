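Package: gaitpolar
Title: Polar Gaitogram Analysis of Insole Ground-Reaction-Force Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gait-disorder assessment from multi-sensor insole ground-reaction-force
    (GRF) recordings. Extracts the signed medial-lateral centre of pressure (COPx),
    estimates a continuous gait phase with an adaptive frequency oscillator, builds
    the polar gaitogram (gait phase as angle, |COPx| as radius), and computes the
    area ratio index (ARI) and tangent-line angle together with the reference
    indices PPD (plantar pressure difference) and PCI (phase coordination index).
    Includes threshold-based classification of the affected side, exact
    Mann-Whitney group comparison, a seeded synthetic-gait generator with known
    ground truth, and ggplot2 visualisations.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
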