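Package: qctscreen
Title: Opportunistic Osteoporosis Screening from Routine CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for opportunistic quantitative-CT (QCT) osteoporosis
    screening. Converts CT attenuation to volumetric bone mineral density
    (vBMD) via asynchronous linear calibration with contrast-phase
    correction, reduces labelled vertebral segmentation masks to the
    trabecular compartment by metric (anisotropic) erosion, computes
    trabecular and integral vBMD, bone mineral content and virtual
    DXA-equivalent areal BMD, and provides the fracture-association
    statistics used in prevalent-fracture studies: standardized logistic
    odds ratios, ROC/AUC with DeLong variance and paired DeLong tests, and
    an ROC-distance procedure for transferring diagnostic vBMD cutoffs
    between bone measures. Includes a seeded digital-phantom and synthetic
    cohort generator so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
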