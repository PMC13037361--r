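Package: actikoa
Title: Diurnal Wrist-Accelerometry Profiles for Early Knee Osteoarthritis
    Risk Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying whether 24-hour wrist-accelerometry activity
    profiles carry an early movement signature of knee osteoarthritis (KOA).
    Provides a seeded synthetic-cohort generator with a realistic diurnal
    template, seasonal modulation and a calibratable case attenuation; cohort
    construction with eligibility filtering (anomalous readings, BMI cutoff),
    ICD-10 based disease-status labelling and covariate-matched
    undersampling; a multi-modal 1D convolutional classifier that fuses the
    hourly activity profile with month/sex embeddings and an age/weight
    projector, trained with Adam; and stratified k-fold cross-validation with
    accuracy, macro F1, macro sensitivity, macro AUC, confusion matrices and
    the associated chi-squared and proportion z significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
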