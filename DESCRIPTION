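Package: endorisk
Title: Integrated Histomolecular Risk Classification of Endometrial Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for TCGA-surrogate molecular classification of endometrial
    carcinoma (POLEmut, MMRd, p53abn, NSMP) from immunohistochemistry and
    targeted POLE sequencing, prognostic risk stratification under the ESMO
    2016 recommendations and the ESGO/ESTRO/ESP 2020 guidelines (with and
    without molecular data), a histopathologic triage algorithm that restricts
    POLE sequencing to cases whose risk class can change, risk-class migration
    analysis, disease-free survival statistics, and a seeded synthetic-cohort
    generator calibrated to a published 211-patient consecutive cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
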