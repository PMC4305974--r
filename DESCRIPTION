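Package: apterms
Title: Generic Reference Terminology Model for Anatomic Pathology Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for postcoordinated terminology in anatomic pathology
    structured reporting. Provides an ontology of observation targets,
    properties and qualifiers with SNOMED CT coded permissible value sets
    (descendants included), a composer and validator for generic observation
    expressions (context + target + property + qualifiers + value), a
    decomposer that maps precoordinated interface-terminology terms to
    generic expressions via an equivalence table, a value-set-uniqueness
    genericity classifier, registry breakdown statistics with SNOMED
    coverage, serializers for JSON, compositional-grammar strings and
    HL7-template-style XML, and a synthetic registry generator for testing
    the whole pipeline without external terminology releases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
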