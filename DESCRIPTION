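Package: ivimroi
Title: IVIM and ADC Fitting of Multi-b-Value Diffusion MRI with ROI
    Reproducibility and Diagnostic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constrained bi-exponential intravoxel incoherent motion (IVIM)
    and mono-exponential apparent diffusion coefficient (ADC) fitting of
    multi-b-value diffusion-weighted MRI, voxelwise and on region-of-interest
    (ROI) averaged signals; a synthetic thyroid-nodule phantom generator with
    Rician noise, cystic subregions and a two-observer/two-session ROI
    delineation model; whole-lesion versus single-section ROI aggregation;
    reproducibility statistics (two-way random absolute-agreement intraclass
    correlation, Bland-Altman limits of agreement, normality and group
    tests); and benign-versus-malignant diagnostics (empirical ROC, DeLong
    AUC variance and comparison test, Youden-optimal cutoffs, logistic
    marker combination). An end-to-end seeded study pipeline emulates a
    two-reader diffusion MRI reproducibility study and writes its report
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
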