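Package: fibropet
Title: Quantitative PET/CT Analysis of Collagen-Targeted Imaging in
    Experimental Lung Fibrosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying collagen-targeted PET/CT imaging in
    the bleomycin mouse model of pulmonary fibrosis: Hounsfield-unit
    density segmentation of lung CT into aerated and non-aerated
    compartments, decay-corrected percent-injected-dose-per-gram (%ID/g)
    uptake quantification, dynamic time-activity curve analysis, ex vivo
    biodistribution ratios, and the nonparametric longitudinal statistics
    used for therapy-monitoring and progression-prediction studies. A
    digital mouse-thorax phantom generator produces synthetic CT and
    dynamic PET cohorts with known ground truth for validating every
    step of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
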