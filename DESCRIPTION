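Package: stcorr
Title: Spatio-Temporal Correlations in Long-Term Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies temporal correlations (autocorrelation half-decay of
    broadband gamma-power), spatial correlations (distance-binned pairwise
    cross-correlation) and Hurst exponents in multichannel intracranial EEG,
    with time-shuffled surrogate controls, band-ratio slow-wave-sleep staging,
    region assignment along the cortical functional hierarchy and the
    associated paired statistics. Includes a probabilistic excitable-lattice
    network model whose connectivity eigenvalue tunes the distance to
    criticality, reproducing the joint increase of spatial and temporal
    correlations near the critical point, and a synthetic iEEG generator with
    known ground-truth correlation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    arrow,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
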