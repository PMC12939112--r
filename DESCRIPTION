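Package: pulmovasc
Title: Quantitative Pulmonary Vessel Morphology and Diagnostic Statistics for Thoracic CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated quantitative analysis of the peripheral pulmonary
    vasculature on contrast-enhanced thoracic CT. Segments lungs and airways by
    attenuation, enhances tubular structures with a multiscale Hessian
    (Frangi-type) filter over the 2-10 mm diameter range, links regularly
    spaced vesselness maxima into optimized centerline forests, separates
    arteries from veins with an exact integer program combining intertwined
    spatial distribution and artery-alongside-bronchus evidence, and computes
    diameter-binned morphometric readouts (segment counts, vessel density per
    litre of lung, normalized vessel volume, sum-of-angles tortuosity,
    artery-to-vein differences and ratios). Cohort-level tools provide
    Spearman correlations, Wilcoxon/Kruskal-Wallis tests with Dunn-Bonferroni
    post hocs, ROC analysis with DeLong variance and AUC comparison, and
    logistic risk-score marker combination, together with synthetic CT
    phantoms and synthetic cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    ggplot2,
    generics,
    glmnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
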