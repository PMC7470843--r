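Package: spbquant
Title: Quantitation of Spindle Pole Body Plaque Asymmetry from 3D Fluorescence Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of spindle pole body (SPB) structural
    asymmetry from dual-channel 3D fluorescence stacks of budding yeast.
    Implements 3D Gaussian spot fitting of SPB foci, realignment of each
    image along the inter-SPB (or inner-outer plaque) axis with the old SPB
    on the left, class averaging, linescan intensity profiling with plaque
    peak assignment, inner:outer plaque intensity ratios, a fold-change
    asymmetry index with mode classification, spindle-length cell-cycle
    staging, and a lower-resolution wide-field quantitation path (maximum
    projection, windowed integrated intensity with background subtraction,
    reference-normalized asymmetry). A ground-truthed synthetic image
    generator emulates SIM-like stacks of SPBs across the duplication and
    spindle cycle so the whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    methods,
    minpack.lm,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
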