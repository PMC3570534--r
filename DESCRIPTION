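Package: lakescape
Title: Soundscape Analysis of Freshwater Lakes Along Urbanization Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for ecoacoustic analysis of lake soundscapes: reading and
    writing PCM WAV recordings, short-time power spectral density estimation,
    per-kilohertz band power and the anthrophony (1-2 kHz relative power) and
    biophony (maximum 3-8 kHz relative power) indices, diel-period
    aggregation, threshold-exceedance summaries, and a permutation-based
    inferential layer (multiple regression on period means, PCA with
    permutation significance, PERMANOVA, and PERMDISP). Includes a
    deterministic synthetic-soundscape generator that injects known
    anthrophony, biophony, and wind-gust structure across an urbanization
    gradient so that every stage of the pipeline can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
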