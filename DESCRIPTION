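Package: regionscore
Title: Atlas-Region Overlap Scoring of Lesion Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-level evaluation of how well a preoperative lesion mask
    (for example the FLAIR-hyperintense extent of a glioblastoma) predicts
    where tumor recurrence later appears. Standard-space parcellations
    (AAL3- and JHU-ICBM-DTI-81-style integer label volumes) are projected
    onto paired primary-tumor and recurrence masks; each atlas region is
    classified as a true/false positive/negative, and sensitivity,
    specificity, positive and negative predictive value are computed per
    patient and for the cohort (pooled and patient-averaged). Includes
    NIfTI mask and label-volume I/O, application of FLIRT-style affine
    transforms by nearest-neighbour or trilinear resampling, clinical-table
    descriptives, and a seeded synthetic cohort generator with full ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
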