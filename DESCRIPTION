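Package: fluortrack
Title: Cell Tracking and Behavior Classification for Multichannel
    Fluorescence Time-Lapse Microscopy of Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks thousands of cells in multichannel fluorescence
    time-lapse image stacks of stimulated tissue, extracts per-cell
    intensity traces, detects transient and step features, and assigns
    each cell to one of twelve behavior categories with a rule-based
    decision tree, mapping category frequency onto tissue location.
    Includes a synthetic-scene generator that renders ground-truth image
    stacks so every stage of the pipeline can be validated against known
    truth: centroid localization on the summed-channel image, nearest
    neighbor linking with gap memory, linear gap interpolation, static
    phase track extension, tiled-grid background subtraction, 3x3
    neighborhood intensity extraction, prominence-filtered peak
    detection, penalized piecewise-linear changepoint detection, and
    spatial binning of classified behaviors.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
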