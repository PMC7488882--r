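Package: strokeclock
Title: MRI-Based Stroke Onset Timing on Synthetic Multiparametric Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pre-registered multiparametric MR brain volumes (multi-echo T2,
    multi-b-value diffusion, FLAIR) for hyperacute ischemic stroke cohorts, computes
    quantitative maps (ADC, mean diffusivity, effective DWI, echo-summed T2w, voxelwise
    mono-exponential T2), segments the ischemic lesion with adaptive ADC/T2 threshold
    rules and a mirrored contralateral reference volume of interest, derives
    ischemic-to-nonischemic image intensity ratios per patient, and evaluates the
    ratios as classifiers of whether a patient is within the 4.5-hour thrombolysis
    window: correlations, ROC/AUC with confidence intervals and paired nonparametric
    comparison, Youden-index cutoffs, diagnostic metrics, logistic regression with
    AICc, precision-recall-gain curves, F1 scores, and free-marginal multirater kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    minpack.lm,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
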