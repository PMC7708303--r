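Package: emrpheno
Title: Longitudinal Electronic-Medical-Record Phenotyping and Time-Resolved
    Gene-Phenotype Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps coded clinical diagnoses from electronic medical records to
    Human Phenotype Ontology terms, propagates ancestral terms, bins phenotypes
    into 3-month age intervals between birth and 25 years, conditions on
    per-individual EMR-usage windows, and detects time-resolved gene-phenotype
    associations with two-sided Fisher exact tests, max-over-time selection and
    Benjamini-Hochberg false-discovery-rate control. Includes a synthetic
    EMR-cohort generator with planted time-localized effects so that every
    pipeline stage can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
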