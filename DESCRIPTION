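Package: cardioratio
Title: Ratiometric Calcium Imaging Analysis for the Larval Zebrafish Heart
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cardiac optical mapping of the larval zebrafish heart
    with ratiometric genetically encoded calcium indicators. Converts
    dual-emission-channel fluorescence movies into motion-robust calcium
    ratio traces (channel registration, pixel-wise ratioing with a validity
    mask, intensity-weighted region-of-interest averaging), extracts
    calcium-transient kinetics (systolic and diastolic ratio, transient
    amplitude, atrial transient frequency) and atrioventricular conduction
    block calls, measures chamber morphometry (fractional area change),
    quantifies aequorin bioluminescence as the consumption-normalised
    L/Lmax calcium proxy, and applies a normality-gated statistical layer
    for group comparisons. A synthetic beating-heart movie generator with
    full ground truth makes every stage of the pipeline testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    grDevices,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    multcomp,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
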