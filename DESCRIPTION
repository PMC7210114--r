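Package: fpbench
Title: Face-Patch Tuning Benchmarks for Layered Vision Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether layers of a feedforward vision model
    reproduce the population tuning properties reported for macaque
    face patches (ML, AL, AM). Provides parametric stimulus generators
    (procedurally rendered annotated faces, multi-view face sets,
    19-parameter cartoon faces, 11-part mosaic faces with a covering
    design), an active-appearance-model style 50-dimensional
    shape-appearance face space with piecewise-affine warping, extraction
    of face-selective units via the face-selectivity index, the full set
    of per-population tuning statistics (response similarity matrices,
    size-invariance index, spike-triggered averages and shape-preference
    index, cross-view STA correlations, smoothed cartoon tuning curves
    with permutation significance, contrast-polarity preferences), and
    layer-versus-patch comparison statistics with randomized null bands
    and bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    png
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
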