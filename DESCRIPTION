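Package: diaphragmotion
Title: Diaphragm Motion and Shape Quantification from Dynamic Sagittal Lung
    Segmentations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies diaphragm motion and shape from ordered series of 2D
    binary lung segmentation masks acquired by dynamic sagittal chest MRI
    between end-expiration and end-inspiration. Extracts sub-pixel lung
    contours, detects anatomical reference points (lung apex, centroid,
    anterior and posterior costophrenic angles, raw and derived diaphragm
    apex) after ellipse-based orientation normalization, and computes four
    thorax-related and four diaphragm-related outcomes as
    inspiration/expiration ratios or displacements. Includes a parametric
    respiratory-motion phantom with analytically known outcomes for
    verification, cohort simulation with pulmonary-function covariates, and
    the validation and cohort statistics used with such measurements
    (two-way mixed absolute-agreement intraclass correlation, Bland-Altman
    limits, Spearman correlation tables, covariate-adjusted group
    comparison with Bonferroni-corrected pairwise contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    png,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ImageAnalysis, Segmentation, Visualization
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'stats.R'
    'geometry.R'
    'landmarks.R'
    'outcomes.R'
    'segmentation-io.R'
    'phantom.R'
    'cohort.R'
    'cli.R'
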