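Package: paleoseas
Title: Paleoseasonality from Sequentially Sampled Tooth Enamel Isotopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs seasonal paleotemperatures from intra-tooth oxygen
    isotope (d18O) series of herbivore tooth enamel. Fits sinusoidal seasonal
    models to sequentially sampled enamel d18O, corrects seasonal amplitude for
    damping caused by enamel mineralization time-averaging and drill-sampling
    geometry, converts corrected summer-peak and winter-trough values to air
    temperatures through affine enamel-to-drinking-water and water-to-temperature
    calibrations with Monte-Carlo compound-error propagation, and reproduces the
    supporting analyses of such studies: per-layer summaries, one-way ANOVA,
    Levene and Tukey HSD tests, Cohen's d effect sizes, winter-d18O versus
    collagen-d13C correlation, strontium isotope locality screening, and
    collagen quality control. A synthetic-data generator emulates the full
    forward model so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
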