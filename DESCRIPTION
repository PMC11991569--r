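Package: npvleak
Title: Leak Flow Compensation and Tidal Volume Estimation for
    Nasopharyngeal Ventilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs leak flow, respiratory flow and tidal volume
    during nasopharyngeal ventilation from two monitored signals: the
    pharyngeal pressure and the flow through the nasopharyngeal tube.
    The leak channel is modelled by the Rohrer flow-pressure relation,
    characterised during an apnoeic stepped-flow protocol and inverted
    sample by sample during breathing.  Includes a lumped-parameter
    (electrical-analog) simulator of the ventilation bench that generates
    synthetic waveforms for spontaneous and mandatory breathing, breath
    segmentation and tidal-volume integration, and a validation layer
    (relative error, coefficient of variation, pooled and paired t tests)
    reproducing a bench comparison against a gold-standard flow sensor.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
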