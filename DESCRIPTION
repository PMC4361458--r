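Package: prcclamp
Title: Phase Response Curve Estimation Under Closed-Loop Frequency Clamp
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of phase response curves (PRCs) of tonically firing
    neurons from perturbation experiments, together with an in-silico
    closed-loop laboratory for validating every estimator against a known
    ground truth. Implements the corrected direct method (first- and
    second-order phase samples joined to remove the sampling bound near the
    end of the firing cycle), Gaussian-kernel smoothing with a data-driven
    bandwidth and bootstrap confidence bands, the weighted spike-triggered
    average (WSTA) indirect estimator driven by Ornstein-Uhlenbeck current
    noise, and scalar PRC-shape summaries (peak-to-baseline ratio, sigmoid
    fit of its rate dependence, peak-time transform). The simulation side
    provides a phase-oscillator neuron with prescribed PRC, a
    conductance-based surrogate with a channel-noise diffusion
    approximation, a PID frequency clamp with Sobol-scheduled reactive
    perturbations, and a state-save replay protocol.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
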