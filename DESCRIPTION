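Package: spncad
Title: Computer-Aided Detection of Solitary Pulmonary Nodules in PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided detection (CAD) pipeline for solitary pulmonary
    nodules (SPNs) in paired PET/CT slices. Implements iterative
    dynamic-threshold lung parenchyma segmentation on CT, rigid PET-to-CT
    registration by mutual-information maximisation with a Powell
    direction-set optimiser, marker-controlled immersion watershed
    delineation of PET-flagged nodule candidates, gray-level co-occurrence
    matrix (GLCM) texture features plus maximum standardized uptake value
    (SUVmax) quantification, and RBF-kernel support-vector-machine
    classification with scan-grouped 10-fold cross-validation. Includes a
    deterministic paired CT/PET digital thorax phantom with ground-truth
    nodule masks for end-to-end evaluation (sensitivity and false positives
    per scan).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
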