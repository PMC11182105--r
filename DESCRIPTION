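Package: ocuflow
Title: Layer-Specific Retinal and Choroidal Blood Flow from Arterial
    Spin Labeling MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification of retinal and choroidal blood flow from
    arterial spin labeling (ASL) MRI of the posterior eye. Converts
    control/label/M0 image series into quantitative blood-flow maps with a
    single-compartment model, virtually flattens the curved retina to
    extract depth profiles perpendicular to the retinal surface, and
    summarises each vascular layer either by its peak blood flow
    (mL/mL/min) or by depth-integrated blood flow per retinal surface area
    (uL/mm^2/min), a metric designed to resist partial-volume blurring of
    thin layers. Includes a k-space-truncation simulation of acquisition
    resolution, a synthetic eye-phantom generator with known ground truth
    for end-to-end validation, and the group statistics used in ocular
    blood-flow studies (eye-averaged effect sizes, noncentral-t and
    noncentral-F sample-size estimation, mixed models over both eyes, and
    blood-flow/intraocular-pressure association).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    RNifti,
    yaml,
    jsonlite,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, Visualization, Preprocessing
RoxygenNote: 7.3.3
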