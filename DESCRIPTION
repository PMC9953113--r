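Package: rheis
Title: Skin Irritation Prediction on Reconstructed Human Epidermis from
    Impedance Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for predicting skin irritation of chemicals
    from electrochemical impedance spectroscopy (EIS) of reconstructed human
    epidermis (RhE) models. Converts frequency sweeps of complex impedance to
    apparent capacitance, normalizes post-exposure sweeps against each
    tissue's pre-exposure baseline, selects the peak-response frequency,
    derives irritancy cut-offs by ROC analysis, and scores predictive
    performance and within-laboratory reproducibility against OECD Test
    Guideline 439 acceptance bounds. A two-compartment equivalent-circuit
    simulator generates complete synthetic studies (chemical x run x
    replicate x time grids of impedance spectra) so the whole pipeline can be
    exercised and validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
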