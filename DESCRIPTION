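Package: aqsafe
Title: Free-Text EHR Surveillance of Aqueous Humor Liquid Biopsy Safety
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based free-text surveillance of electronic health record
    (EHR) operative reports and clinical notes to establish the safety of
    anterior-chamber (aqueous humor) liquid biopsies. Provides a seeded
    synthetic EHR corpus generator with planted ground truth emulating a
    1418-case surgical cohort, negation-aware complication term flagging
    with evidence spans, anesthesia-type classification from the operative
    report's anesthesia section with no-hit and "general"-misuse review
    rules, biobank-to-EHR record linkage tolerant of data-entry errors,
    temporal adjudication of endophthalmitis mentions against the procedure
    date, follow-up retention arithmetic, exact (Clopper-Pearson) interval
    estimates of complication rates, and a seeded manual-audit protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
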