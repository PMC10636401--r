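Package: anchordecomp
Title: Decomposing Perceptual Anchoring into Bias and Sensitivity Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-phase perceptual anchoring experiments
    in which observers first judge a visual feature percentage relative to a
    numeric anchor and then give an absolute estimate. Fits per-participant,
    per-anchor logistic psychometric functions to the relative judgments and
    linear psychophysical functions to the absolute estimates, extracting the
    point of subjective equality (PSE, response bias) and difference limen
    (DL, sensitivity) from each. Locates the point of maximal uncertainty
    (PMU) in log reaction-time curves via waveform-moment (centroid) analysis
    with a quadratic-vertex cross-check, and provides the within-subject
    inferential layer: 7x7 repeated-measures ANOVA with partial eta squared
    and the ordered linear anchor contrast. Includes a synthetic observer
    cohort generator mirroring the 7 anchors x 7 feature percentages x 7
    exemplars within-subject design, so the whole pipeline is testable by
    parameter recovery without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
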