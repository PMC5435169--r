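Package: seqconfounds
Title: Simulating and Diagnosing Positional-Code Confounds in Sequence fMRI Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative simulations of voxel responses to sequentially
    presented items, together with the confound processes that can masquerade
    as a neural positional code: uniform sensory adaptation, position-tuned
    voxels, differential two-population signals, additive and proportional
    between-item interference, task-phase selectivity, and temporal mixing
    introduced by hemodynamic-response convolution. A diagnostic battery
    (per-event z-scoring, cross-validated shrinkage linear-discriminant
    decoding of item and position, between-trial positional pattern
    similarity and its lag slope) shows which confounds each control removes
    and which survive, so that claimed positional codes can be stress-tested
    against position-collinear read-outs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Classification, Neuroscience
RoxygenNote: 7.3.3
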