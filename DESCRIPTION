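Package: microcosmr
Title: Simulation, Tracking and Density-Dependent Demography of Protist Microcosms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for microcosm experiments that link density-dependent
    demography to movement and morphology traits of unicellular organisms.
    Includes a synthetic experiment generator (logistic population growth,
    correlated-random-walk swimmers, dark-field image rendering), a particle
    tracker (detection, linking, trajectory metrics, quality control), dilution
    assay demography (per-capita growth rate regression, influence diagnostics,
    carrying capacity with delta-method variance), a standardized
    survival-strategy trait index, factorial ANOVA tables with partial eta
    squared, and AICc selection among linear models linking demographic
    parameters to trait-index responses.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    EBImage,
    jsonlite,
    readr,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
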