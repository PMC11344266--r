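Package: dwifov
Title: Field-of-View Extension for Brain Diffusion MRI by 2.5D Conditional
    Adversarial Slice Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Imputes missing axial slices of diffusion-weighted MRI volumes
    whose field of view (FOV) was truncated at the superior or inferior end
    of the brain, conditioning on a co-registered structural (T1-weighted)
    image. A 2.5D conditional adversarial model predicts each sagittal and
    coronal slice from a thin stack of neighbouring diffusion and structural
    slices; four generators (b0 and diffusion-weighted shell, sagittal and
    coronal view) are merged by voxel averaging and recombined with the
    acquired data so that acquired voxels are never modified. Includes NIfTI
    and FSL gradient-table input/output, intensity normalization, brain
    masking, FOV-cutoff simulation, masked MSE/PSNR/3-D SSIM evaluation,
    distance-stratified performance curves, per-direction apparent diffusion
    coefficient analysis with a Kruskal-Wallis test, and a synthetic tensor
    phantom generator for training and validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    RNifti,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
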