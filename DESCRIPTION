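Package: coccosims
Title: Trace-Element Quantification in Individual Coccoliths from NanoSIMS Ion-Count Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies Na/Ca, Mg/Ca, K/Ca, Sr/Ca and Ba/Ca ratios in
    individual coccoliths from multi-plane NanoSIMS ion-count image stacks.
    Provides a ground-truthed synthetic stack generator with Poisson counting
    noise, beam point-spread blur, yield drift and sputtering contaminants;
    plane alignment and automated segmentation of coccolith, contaminant and
    background regions; depth-profile quality control via a coefficient of
    variation corrected for Poisson counting statistics with stable-window
    selection; Ca-gated accumulation of ion counts with correction of the
    mass-88 calcium-dimer interference and calibration to molar ratios; and
    cohort statistics (within- versus among-coccolith variability, log-ratio
    ANOVA with Tukey compact letter displays, correlation screens, culture
    growth rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
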