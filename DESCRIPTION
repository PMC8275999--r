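Package: mepm
Title: Multilevel Mediation Effect Parametric Mapping for Trial-Wise fMRI Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multilevel mediation analysis of trial-wise brain
    imaging experiments in which a manipulated stimulus property (e.g.
    adjective valence) predicts a binary behavioral choice through
    stimulus-evoked brain activity. Implements single-trial GLM construction
    with canonical double-gamma HRF and temporal-derivative basis, motion and
    collinearity quality control (framewise displacement outliers, trial-wise
    variance inflation factors, PCA noise diagnostics), voxel-wise
    Baron-Kenny path fitting with bias-corrected accelerated (BCa) bootstrap
    inference, group-level consistency/covariance decomposition of the
    indirect effect with sign-pattern subgrouping, map thresholding (BH-FDR,
    three-map conjunction, Monte-Carlo cluster-extent calibration),
    behavioral self-bias scoring, logistic prediction of subgroup membership,
    and signed node-strength summaries of effective-connectivity parameter
    tables. A synthetic-data generator with known mediation ground truth
    supports power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), boot, RNifti, optparse, jsonlite, withr,
    knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
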