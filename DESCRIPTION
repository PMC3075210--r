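Package: txcycle
Title: Dynamic Analysis of Stochastic Transcription Cycles from Dual-Reporter Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing time-dependent transcription rates from
    single-cell reporter-protein time series and for characterising the on/off
    switch dynamics that drive transcriptional cycling. Includes a synthetic-data
    generator for telegraph-type switch processes with a refractory period,
    estimation of reporter mRNA and protein degradation rates from inhibitor
    decay experiments, spline-based ODE inversion to recover transcription
    profiles, reversible-jump MCMC inference of binary switch times and levels,
    off-time memory-function analysis, autocorrelation-based period estimation,
    and windowed rank-correlation analysis of dual reporters with bootstrap
    population summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
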