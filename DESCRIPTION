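Package: strokebnm
Title: Brain Network Models of Stroke, Rewiring and Peri-Infarct Slow Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Connectome-based modelling of functional reorganisation after
    focal cortical stroke. Provides a stochastic Kuramoto brain-network
    simulator on weighted directed connectomes, structural lesion and
    rebound-rewiring operators, phase-locking-value (PLV) functional
    connectivity with surrogate significance testing, and a grid fit of
    lesion parameters to observed FC changes. A second, local-scale model
    couples an adaptive exponential integrate-and-fire (adex) network of
    regular- and fast-spiking neurons to a calcium/GCaMP6f fluorescence
    forward model, reproducing the anesthesia-dependent slowing of
    cortical slow oscillations via spike-frequency adaptation. Synthetic
    data generators make every pipeline stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
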