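Package: phasicfmri
Title: Phasic-Alertness fMRI Fatigue Pipeline with Cubic-Grid ROIs
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline relating task-evoked brain activity to
    self-reported fatigue in brain tumor patients. Generates event-related
    phasic-alertness task designs (cue-only and cue-plus-stimulus trials in
    runs enveloped by rest blocks), builds GLM design matrices with the
    canonical double-gamma hemodynamic response and a discrete-cosine
    high-pass basis, fits voxelwise first-level GLMs with percent-signal-change
    transforms, aggregates signal on a systematic cubic-grid ROI atlas with
    hotspot selection, mirror-ROI completion and network allocation
    (central executive vs default mode), scores the 20-item Multidimensional
    Fatigue Inventory, and runs Spearman brain-behavior correlations under a
    two-main-test Bonferroni scheme with conditional follow-ups. Includes a
    synthetic-cohort generator (autocorrelated noise, drift, planted network
    effects and fatigue coupling, ellipsoidal tumor masks) for end-to-end
    validation, plus minimal NIfTI-1 and BIDS-style events I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
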