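Package: perceptime
Title: Clock-Free Duration Estimation from Accumulated Perceptual Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates subjective duration estimation without a pacemaker or
    internal clock. Video-driven activation streams from a layered perceptual
    feature hierarchy are reduced to per-layer Euclidean change series; a
    stochastic, exponentially decaying threshold per layer flags salient
    perceptual changes, which are accumulated and calibrated to seconds with
    epsilon support vector regression under cross-validation. Includes
    gaze-contingent input gating (centre crop, gaze patch, shuffled-gaze
    control), global attention modulation of the thresholds, synthetic
    stimulus generators (activation streams, pixel videos, gaze traces), and
    an experiment harness reproducing characteristic psychophysical patterns
    such as Vierordt-type regression to the mean, scalar variability and
    scene-dependent duration biases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
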