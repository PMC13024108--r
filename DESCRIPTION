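Package: kinemark
Title: Markerless Lower-Limb Joint Kinematics and Clinical Agreement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns pose-landmark time series from markerless motion capture into
    gap-filled, low-pass-filtered hip, knee and ankle joint-angle series and
    range-of-motion summaries, and compares the resulting measurements against
    clinical goniometry with method-comparison statistics: single-measure
    absolute-agreement intraclass correlation ICC(A,1) with F-based confidence
    intervals, Bland-Altman bias and limits of agreement, proportional-bias
    regression, and error-versus-covariate analysis. Includes a synthetic
    motion generator with known kinematic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
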