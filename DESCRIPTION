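Package: lfogcnet
Title: Directed Low-Frequency Connectivity of the Motor Network via
    Spectral Granger Causality
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Parametric spectral Granger causality analysis of
    low-frequency (0.04-0.1 Hz) oscillations in regional brain time
    series, built around a five-node motor-execution network (LM1, RM1,
    LPMC, RPMC, SMA).  Provides a ground-truth vector-autoregressive
    simulator with band-limited innovations, sphere-ROI extraction and
    band-pass preprocessing with motion exclusion, the Geweke
    decomposition of total interdependence into directed and
    instantaneous components, band-integrated causal flow with
    permutation-null significance thresholds, percent
    difference/modulation statistics across groups, network-level t
    tests, and brain-behavior correlation, together with an end-to-end
    study pipeline.
License: MIT + file LICENSE
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
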