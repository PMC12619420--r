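Package: flowcfr
Title: Counterfactual Respiratory-Support Recommendations with Guideline Enforcement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Individualized treatment-effect estimation for the choice between
    noninvasive ventilation (NIV) and high-flow nasal cannula (HFNC) in ICU
    patients at risk of invasive mechanical ventilation. Implements a
    three-stage counterfactual estimator (balanced representation learning
    with an integral probability metric penalty, conditional normalizing
    flows for outcome modelling, and an interventional latent adjustment for
    unmeasured confounding), a deterministic rule engine encoding ERS/ATS
    2017 NIV and ERS 2022 HFNC guideline criteria with a
    block/correct/defer audit of model recommendations, a concordance-versus-
    outcome evaluation with covariate-adjusted odds ratios, and a synthetic
    ICU cohort simulator with known counterfactual ground truth for offline
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    boot,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
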