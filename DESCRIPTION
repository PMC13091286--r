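Package: breastplanr
Title: Plan Evaluation and Workflow Simulation for Deep-Learning Breast Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dose-volume-histogram clinical-goal scoring, EUD-based tumour
    control probability, linear excess-risk normal-tissue complication models,
    contour-similarity metrics (volumetric and surface Dice, 95th-percentile
    Hausdorff distance), and a workflow route-decision and time model for
    left-sided breast radiotherapy plans produced with deep-learning
    segmentation and planning. Includes a synthetic-cohort generator (voxel
    phantoms, plan-like dose fields, contour perturbations) so the whole
    pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
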