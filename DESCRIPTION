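Package: voltconn
Title: Spike Detection and Functional Connectivity from Voltage Imaging
    of Neuronal Microislands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-speed voltage-imaging recordings of
    complete neuronal networks grown on patterned microislands. Extracts
    background-corrected fluorescence and dF/F traces from multi-frame TIFF
    movies and neuron/background regions of interest, detects action
    potentials by one-dimensional k-means classification of dF/F samples
    followed by a signal-to-noise threshold, computes firing-rate and
    inter-spike-interval statistics, spike-time tiling coefficients, lag-time
    histograms, and a directed cross-correlation index (XCI) of monosynaptic
    connectivity between identified hippocampal cell types. A ground-truth
    branching-network simulator generates synthetic microislands, spike
    trains, and rendered voltage-dye traces and movies for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
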