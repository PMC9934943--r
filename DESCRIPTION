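Package: lungqct
Title: Precision of Quantitative CT Measures of Lung Aeration and Alveolar Recruitment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies lung aeration from thoracic CT volumes and binary lung
    segmentation masks: gas/tissue fractions, the four Hounsfield-unit aeration
    compartments, lung weight, end-expiratory lung volume, PEEP-induced alveolar
    recruitment, tidal recruitment and tidal hyperinflation. Quantifies agreement
    between segmentation masks by Dice overlap and exact average/maximum symmetric
    surface distances under the 26-neighborhood surface definition. Estimates
    measurement precision (Bland-Altman bias, repeatability and reproducibility
    coefficients with BCa bootstrap confidence intervals, sample-size planning)
    from paired per-patient measurements, and generates synthetic lung phantom
    cohorts with programmed recruitment and an observer boundary-perturbation
    model so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
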