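Package: fractalEEG
Title: Higuchi Fractal Dimension Markers and Transferable Classification
    for Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying non-linear, non-oscillatory complexity markers
    in multichannel electroencephalography (EEG) recorded during motor
    imagery, as used in the search for diagnostic and prognostic biomarkers
    of central neuropathic pain after spinal cord injury. Implements the
    Higuchi fractal dimension estimator on overlapping 2-second epochs,
    electrode-wise bootstrap tests of group mean differences with Bonferroni
    correction, nu-SVC classification with greedy forward channel selection
    under nested leave-one-subject-out cross-validation, majority-vote
    participant-level prediction, and channel/offset transfer between
    cohorts. A seeded synthetic-data module generates group-structured EEG
    epoch datasets from fractional Brownian motion, whose exact fractal
    dimension (D = 2 - H) provides ground truth for estimator and pipeline
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    e1071,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'classify.R'
    'fbm.R'
    'fractalEEG-package.R'
    'groupcompare.R'
    'hfd.R'
    'io.R'
    'montage.R'
    'pipeline.R'
    'synthdata.R'
    'utils.R'
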