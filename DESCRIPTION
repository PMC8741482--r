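Package: dysfscreen
Title: Membrane-Localization Scoring and Repair Kinetics for Dysferlin Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying plasma-membrane localization of dysferlin
    missense variants from bicistronic reporter flow cytometry (surface-label /
    DsRed geometric-mean fluorescence ratios normalized to wild type), for
    classifying variants against a 25%-of-wild-type threshold, for calling
    chemical-chaperone rescue hits across treatment conditions, and for
    quantifying membrane-repair kinetics from laser-wounding dye-influx
    time-lapse stacks under an exponential-resealing model. Includes seeded
    synthetic-data generators for both the cytometry and the time-lapse assays.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
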