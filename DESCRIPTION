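Package: LFAreader
Title: Semi-Quantitative Lateral-Flow Strip Reading and Analytical Validation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based semi-quantitative readout of lateral-flow
    immunoassay (LFIA) cassettes, built around a 25-hydroxyvitamin D strip
    with a control line, a test line and a five-line printed reference
    ladder. Provides a synthetic strip-image generator with exhaustively
    known ground truth; classical strip detection and perspective
    rectification; background-corrected line-signal extraction; per-image
    multi-point intensity calibration, concentration regression and
    three-level clinical classification (deficient/insufficient/sufficient);
    a learned cross-device photometric alignment (sRGB linearization,
    neutral-zone white balance, polynomial shading correction, 3x3 color
    correction matrix); and the analytical-validation statistics layer
    (CLSI EP17-A2 limit of blank/detection, percent agreement, Wilson score
    intervals, Cohen's kappa, Pearson correlation, Welch confidence
    intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Visualization, QualityControl, Classification
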