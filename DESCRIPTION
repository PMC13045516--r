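Package: blademri
Title: Quantitative Bladder Multiparametric MRI Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Voxelwise model-based quantification of bladder multiparametric
    MRI together with a deep-feature classification pipeline. Diffusion-weighted
    series are fitted with monoexponential (ADC) and non-Gaussian intravoxel
    incoherent motion (f, D*, D, K) models; dynamic contrast-enhanced series are
    quantified via variable-flip-angle T1 mapping, signal-to-concentration
    conversion, Patlak graphical analysis and the extended Tofts model, producing
    parametric maps and ROI statistics from NIfTI volumes. The classification
    path offers backbone-agnostic deep-feature extraction with a deterministic
    stub backbone, five feature-selection scorers (mRMR, ReliefF, chi-squared,
    ANOVA F, Kruskal-Wallis), three classifiers (SVM, decision tree, k-NN) and
    ROC-based evaluation. Seeded digital phantoms with known ground truth make
    every fitter testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    minpack.lm,
    pracma,
    e1071,
    rpart,
    class,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
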