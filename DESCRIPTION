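Package: bcmrenal
Title: Renal Function Prediction from Bioimpedance Body Cell Mass
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts 24-h urinary creatinine excretion, creatinine clearance
    and the glomerular filtration rate (GFR) of chronic kidney disease patients
    from body cell mass (BCM) measured by bioelectrical impedance analysis,
    alongside the classic Cockcroft-Gault and IDMS-traceable MDRD-4 comparator
    equations. Includes the derivation machinery (p-value stepwise multiple
    regression with collinearity diagnostics, univariate GFR ~ BCM/SCr line
    fit), a method-agreement statistics battery (Lin's concordance correlation,
    Bland-Altman limits, RMSE prediction error, percent-within accuracy, ROC
    analysis with DeLong AUC comparison, Hotelling-Williams correlation test)
    and a calibrated synthetic CKD cohort simulator for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pROC,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
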