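Package: microMRS
Title: Single-Cell 1H MRS Metabolic Fingerprinting and Competence Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, feature extraction and classification for single-embryo
    and single-oocyte 1H magnetic resonance spectroscopy (micro-MRS). Provides a
    data model for free-induction decays and 1D 1H spectra with referencing and
    baseline correction; a calibrated synthetic-cohort generator of Lorentzian
    fatty-acid spectra; fourteen chemical-shift-region biomarkers (region
    intensity, lineshape skewness and kurtosis, Lorentzian fit amplitude and
    linewidth) with SNR and linewidth quality control; two-cohort statistics
    (Monte-Carlo Lilliefors normality gate, Welch t, exact Mann-Whitney U); a
    leakage-controlled leave-one-out cross-validated standardize-SMOTE-PCA-SVM
    classification pipeline with a pooled confusion-matrix metric panel, ROC AUC
    and a dummy baseline; and exact Shapley attribution over principal-component
    features by coalition enumeration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nortest,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'spectra.R'
    'biomarkers.R'
    'utils.R'
    'mlpipe.R'
    'attribution.R'
    'stats.R'
    'synthdata.R'
    'pipeline.R'
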