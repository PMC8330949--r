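Package: strabscreen
Title: Automatic Strabismus Screening from Frontal Facial Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens for strabismus (ocular misalignment) from a single frontal
    facial image. Eye regions are extracted from 68-point facial landmarks, the
    iris is segmented by combining Otsu binarization with an HSV dark-pixel mask,
    the pupil center is estimated by a geometric least-squares circle fit to
    limbus boundary samples, and eye alignment is summarized by a positional
    similarity statistic S (the max/min ratio of the two per-eye canthus-distance
    ratios, S >= 1, with 1 indicating symmetric iris placement). Includes a
    synthetic eye/face image generator with exact ground truth for validation,
    one-sided Mann-Whitney cohort testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jpeg,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
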