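Package: bollmark
Title: Detection of Stink Bug Puncture Marks on Cotton Bolls from
    LED-Induced Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for detecting and classifying stink bug
    feeding marks on developing cotton bolls photographed under blue-LED
    induced fluorescence. Converts raw color photographs into masked
    ratiometric (green/red) intensity images, detects candidate fluorescent
    marks with a local-maximum filter, segments each mark with a greedy-snake
    active contour, filters marks by area, intensity, aspect ratio and
    convexity, computes the donut intensity ratio I1/I2, and classifies marks
    with a two-threshold rectangle criterion including contingency tables and
    an ROC rectangle sweep. Ships a calibrated synthetic scene and
    feature-table generator so the whole pipeline is testable without boll
    photographs, and nonparametric group-comparison statistics
    (Kruskal-Wallis, Dunn's post hoc, Wilcoxon signed rank).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    stats,
    grDevices,
    tools,
    utils,
    tiff,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
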