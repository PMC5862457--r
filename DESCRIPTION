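Package: rsmconcord
Title: Rating Scale Model Calibration and Short-Form Concordance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates polytomous Likert questionnaires with the Andrich
    Rating Scale Model via joint maximum likelihood, computes INFIT/OUTFIT
    mean-square fit statistics, person and item separation indices, test
    information functions and item difficulty maps, and quantifies the
    concordance between a full-length instrument and its short form through
    standardized regression of person measures, the Reduction-in-Uncertainty
    index, and an item-efficiency index. Includes a synthetic-data generator
    for known-truth polytomous response matrices with injectable missingness
    and random-responder misfit, so the whole pipeline can be exercised and
    validated without access to raw survey data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
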