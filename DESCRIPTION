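Package: sdohscan
Title: Rule-Based Detection of Social Determinants of Health in Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects documentation of social determinants of health (SDOH) in
    free-text clinical notes with Lucene-style Boolean proximity rules, and
    compares it against structured ICD-10-CM Z-code documentation for a
    primary-care diabetes cohort. Ships seven curated rules covering social
    isolation, employment, housing, food insecurity, education, finance and
    stress; a query parser and proximity match engine; Z-code domain
    classification and cohort selection; prevalence and overlap reporting; and
    chart-review validation statistics (positive predictive value with Wilson
    intervals, observed proportional agreement, Cohen kappa). A synthetic EHR
    generator with planted evidence snippets makes every pipeline stage
    testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
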