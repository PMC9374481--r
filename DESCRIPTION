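Package: megentrain
Title: Visual Entrainment Analysis for MEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for steady-state visual entrainment
    responses in MEG sensor arrays. Implements complex-demodulation
    time-frequency decomposition, baseline normalization, cluster-based
    permutation selection of the entrainment window, DICS (dynamic imaging
    of coherent sources) beamforming with virtual-sensor extraction,
    entrainment read-outs (absolute and baseline-relative amplitude,
    inter-trial phase locking, cross-trial coefficient of variation,
    per-frequency specificity), periodic/aperiodic parameterization of
    baseline spectra, and a group-statistics layer with pooled-variance t
    tests, Cohen's d, JZS Bayes factors and linear regression. A synthetic
    two-group cohort generator with full ground truth supports recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
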