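Package: rheoflow
Title: Microfluidic Optical Viscometry, Micro-PIV and Red Blood Cell
    Aggregate Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measurement chain for low-hematocrit blood microrheology in
    rectangular microchannels: an analytical two-fluid stratified duct-flow
    series solution with a finite-difference cross-check, used as a
    microfluidic co-flow optical viscometer; multi-pass cross-correlation
    micro particle image velocimetry (micro-PIV) with shear-rate estimation
    from velocity-profile slopes; intensity-based segmentation and sizing of
    red blood cell aggregates in bright-field frames; shear-thinning
    rheological model fitting (power law and Carreau) with goodness-of-fit
    reporting; and a synthetic-data generator that produces every input the
    pipeline consumes together with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    minpack.lm,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Visualization
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'coflow.R'
    'velocimetry.R'
    'aggregates.R'
    'rheology.R'
    'synthetic.R'
    'pipeline.R'
    'io.R'
    'rheoflow-package.R'
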