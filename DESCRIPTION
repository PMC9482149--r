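Package: conchvision
Title: Looming-Stimulus Psychophysics and Eye Optics for Conch-Snail Vision
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring spatial resolution and contrast sensitivity of
    camera-type gastropod eyes with expanding ("looming") visual stimuli.
    Generates calibrated loom and isoluminant-checkerboard stimulus frames with
    Michelson-contrast labels, models behavioural trial tables under a
    five-category withdrawal ethogram, infers behavioural thresholds by exact
    tests against a control stimulus with Bonferroni correction, and computes
    anatomical estimates of acuity and optical sensitivity (inter-receptor
    angle, Land's sensitivity equation, retinal cell-census extrapolation,
    acuity-limited image blurring). A synthetic-observer generator with a
    psychometric response model stands in for animal trial data so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
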