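Package: keysal
Title: Saliency-Based Keyframe Extraction for Diagnostic Hysteroscopy Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes diagnostic hysteroscopy (DH) video by extracting
    diagnostically important keyframes with a hybrid visual-saliency model.
    Four per-pixel saliency operators (block-matching motion magnitude,
    entropy-directed texture segmentation, multi-scale color contrast over a
    Gaussian pyramid, and Gaussian-smoothed curvature) are collapsed to
    per-frame scores, normalized, and combined by weighted linear fusion into
    an attention curve from which keyframes are selected either by
    mean-attention thresholding or by per-shot maxima for a requested number
    of keyframes. Includes an evaluation module (tolerance-window matching,
    accuracy, precision, recall, F-measure, ablation tables) and a seeded
    synthetic DH-video generator with planted ground truth so the whole
    pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
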