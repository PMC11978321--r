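Package: afmcell
Title: Single-Cell AFM Indentation Analysis and Actin Network Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch analysis of atomic force microscopy (AFM) force-distance
    curves acquired on single non-adherent cells with a colloidal probe:
    baseline and contact-point correction, cantilever-bending correction,
    Hertz (paraboloid) and exact Sneddon-sphere contact-model fitting of the
    approach segment, per-curve quality control (short baselines,
    membrane-pinching events), per-cell aggregation with inclusion rules,
    Tukey-fence outlier handling with post-hoc z validation, and two-sample
    group comparisons.  A companion image module quantifies the actin network
    from single confocal optical sections (rolling-ball background removal,
    smoothing, thresholding, skeletonization, cortex exclusion, length
    statistics).  Synthetic force-curve and actin-image generators with known
    ground truth make the entire pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rhdf5
Config/testthat/edition: 3
RoxygenNote: 7.3.3
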