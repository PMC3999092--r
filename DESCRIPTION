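Package: plaqueseg
Title: Carotid Plaque Component Segmentation with Registration-Aware Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxelwise segmentation of atherosclerotic plaque components
    (calcification, fibrous tissue, lipid-rich necrotic core) from
    co-registered multi-sequence MRI and CTA, where training labels come from
    imperfectly registered reference segmentations. Implements three
    label-uncertainty training strategies (Gaussian-blurred soft labels with
    per-slice Dice^n weighting, local lumen/outer-wall contour-distance
    weights, and robust Gaussian outlier rejection), sample-weighted linear
    discriminant and instance-weighted RBF support-vector classifiers, a
    volume-based evaluation protocol with leave-one-subject-out
    cross-validation and nested hyperparameter selection, and a synthetic
    vessel-phantom generator with controllable misregistration so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    kernlab,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
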