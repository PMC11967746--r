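Package: cohortbias
Title: Audit Race and Ethnicity Bias of EHR Data-Completeness Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Applies a catalogue of 19 commonly used electronic health record
    data-completeness filters (demographics, medical-interaction records, and
    observation-period spans) to a patient cohort, measures per-race and
    per-ethnicity data availability against an all-patients baseline, and
    tests whether each group is disproportionately excluded relative to a
    baseline group using an exact binomial observed-versus-expected proportion
    test with Bonferroni correction. Includes a seeded synthetic EHR cohort
    generator with configurable group marginals and planted differential data
    availability, so the full audit pipeline can be validated against known
    ground truth, and a command-line interface orchestrating
    generate/audit/test/report runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
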