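Package: driftlab
Title: Tuning Stability and Representational Drift in Visual Cortex Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured calcium-imaging event data
    from primary visual cortex: single-trial two-dimensional Gaussian tuning
    estimation over orientation and spatial frequency with permutation
    goodness-of-fit testing, half-width-at-half-maximum bandwidths, tuning
    stability deltas between sessions, signal-correlation and reliability
    metrics, k-nearest-neighbor stimulus decoding with set-based
    cross-validation, and a fixed-classifier representational-drift metric.
    Includes a synthetic-session generator with full ground truth so the
    entire pipeline is testable end to end without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
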