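Package: trajdec
Title: Continuous Hand-Trajectory Decoding from Low-Frequency EEG with
    Recursive PLS and a Square-Root Unscented Kalman Filter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying across-participant and across-session
    transfer learning in continuous two-dimensional hand-trajectory
    decoding from low-frequency EEG. Provides a synthetic multi-session
    study generator with a known source-to-kinematics coupling, the
    standard low-frequency signal-conditioning chain (band filtering,
    resampling, common average reference, lag embedding), an sLORETA
    inverse kernel with region-of-interest scouting, a recursive
    exponentially weighted partial least squares decoder cascaded with a
    square-root unscented Kalman filter, leave-one-participant-out model
    pooling with four update strategies, trial-shuffled chance-level
    estimation, Wilcoxon/FDR strategy comparisons, and forward-model
    decoding-pattern analysis with a 2-D embedding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
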