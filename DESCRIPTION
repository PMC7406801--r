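Package: neuromkl
Title: Multimodal Neuroimaging Fusion with EasyMKL for Dementia Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multimodal classification of Alzheimer's disease and
    its prodromal stages from structural, metabolic, diffusion and functional
    neuroimaging features together with APOE genotype. Provides a seeded
    synthetic multimodal cohort generator, voxel-level measures (fractional
    anisotropy, mean diffusivity, ALFF, fALFF, regional homogeneity),
    voxel-wise group contrasts with multiplicity correction and cluster
    feature extraction, per-modality kernel construction and convex fusion,
    an EasyMKL maximum-margin multiple kernel classifier with leave-one-out
    regularizer selection, full performance reporting (balanced accuracy,
    sensitivity, specificity, precision, F1, ROC/AUC, Cohen's kappa), and
    density-thresholded brain-graph group analysis with permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
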