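Package: calcimetry
Title: Quantitative Analysis of Calcium Imaging and Invasion in 3D
    Neuron-Glioblastoma Cocultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying functional and morphological readouts of
    three-dimensional neuron-glioblastoma coculture experiments. Implements
    semiautomatic detection of active cells from calcium-indicator time-lapse
    stacks (max-min range projection, lowpass filtering, intensity thresholding,
    median smoothing and particle size gating), per-ROI trace extraction,
    background subtraction, moving-average smoothing, deltaF/F0 normalization
    with linear detrending, prominence-based peak detection with seven peak
    parameters, GFP-mask based separation of tumor and neuron signals, active
    neuronal area percentage, spheroid invasion-rate and 2D coverage
    morphometrics, a log2 fold-change secretion screen, and the nonparametric
    statistical harness (Shapiro-Wilk/Kolmogorov-Smirnov normality selection,
    Mann-Whitney U, Kruskal-Wallis with Dunn's post hoc comparisons). A seeded
    synthetic-data generator emulates every input class so the whole pipeline
    is testable end-to-end without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    nortest,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
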