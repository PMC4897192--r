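Package: chaoglob
Title: Chaotic Global Analysis of Heart Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectrally determined "chaotic global" analysis of short
    RR-interval (heart rate variability) series. Implements normalized
    spectral entropy, spectral detrended fluctuation analysis (sDFA) and
    the spectral multitaper measure (sMTM), each rescaled against matched
    sine-wave and uniform-noise reference signals, and combines them into
    the seven Chaotic Forward Parameters (CFP1-CFP7) used to discriminate
    cohorts such as COPD patients versus healthy controls. Includes the
    accompanying cohort statistics layer (quartile summaries,
    Anderson-Darling and Ryan-Joiner normality screens, Kruskal-Wallis
    tests, correlation-matrix PCA), a seeded synthetic RR cohort
    generator, and a small command-line interface.
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
    nortest,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
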