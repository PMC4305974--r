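# apterms

Generic reference terminology for anatomic pathology (AP) observations.

Structured pathology reporting today mostly uses *precoordinated* interface
terminologies: one enumerated template per organ, disease and feature
(`Breast-In situ neoplasm-Lesion size, largest dimension`), which multiplies
into hundreds of templates with no relationships between them. `apterms`
implements the *postcoordinated* alternative — a compact reference model in
which any AP observation is composed at use time as

```
Observation = Context(locator organ, problem organizer, method)
            + Target of observation      (specimen, lesion, margin, nucleus, ...)
            + Property of observation    (diameter, weight, grade, colour, ...)
            + Qualifiers                 (laterality, invasiveness, "largest", ...)
            + optional Value             (coded concept or quantity)
```

with every slot drawn from SNOMED-CT-coded permissible value sets,
*descendants included*, over an ontology with four relationship types:
`IS_A`, `PART_OF`, `HAS_TARGET` (property → target) and `IS_QUALIFIER_OF`
(qualifier → observation). The package is aimed at terminology developers
and health-informatics engineers who need to compose and validate such
expressions, map precoordinated interface terms back onto them, decide
whether a term is generic (unique value set in every application) or
specific, and serialize the results as JSON, compositional-grammar strings
or HL7-template-style XML.

## What is in the box

* `buildReferenceOntology()` — the packaged ontology: observation targets,
  properties and qualifiers with their printed SNOMED CT codes, organs,
  problem organizers, observation methods, special attributes.
* `composeObservation()`, `subsumes()`, `toSCG()`/`parseSCG()`,
  `expressionToJSON()`/`expressionFromJSON()`,
  `writeExpressionXML()`/`readExpressionXML()` (+ shipped XSD).
* `decomposeTerm()` / `decomposeRegistry()` — precoordinated interface
  terms → generic expressions via a pattern-based equivalence table.
* `classifyGenericity()` — the value-set-uniqueness criterion.
* `registryStats()`, `snomedCoverage()` — registry breakdowns and mapping
  coverage.
* `generateRegistry()` + `defaultProfile()` — synthetic precoordinated
  registries from a composition profile, so the whole pipeline is testable
  without any terminology download.
* A command-line tool (`exec/apterms`): `generate`, `decompose`, `stats`,
  `coverage`, `compose`, `export-xml`, `export-scg`.

## Worked example

The precoordinated interface term
`"Breast-In situ neoplasm-Lesion size, largest dimension"` decomposes into
the generic expression *Diameter of a Lesion, observed by microscopic
investigation, qualified as largest, located in the breast, under a
non-invasive-tumor problem organizer*:

```r
library(apterms)
g  <- buildReferenceOntology()
eq <- loadEquivalenceTable()

term <- precoordinatedTerm("1.3.6.1.4.1.19376.1.8.1.4.164",
  "Breast-In situ neoplasm-Lesion size, largest dimension")
res <- decomposeTerm(term, eq, g)
formatObservation(res@expression)
#> [1] "Diameter (property) OF Lesion (target) QUALIFIED-BY ObservedByMicroscopicInvestigation, largest LOCATOR Breast PROBLEM non-invasive tumor"

toSCG(res@expression)
#> [1] "49755003 |Lesion| : 81827009 |Diameter|, qual = ap:largest |largest|, loc = ap:breast |Breast|, prob = ap:non-invasive-tumor |non-invasive tumor|, method = ap:observedbymicroscopicinvestigation |ObservedByMicroscopicInvestigation|"

toSCG(composeObservation(g, "Specimen", "Weight"))
#> [1] "123038009 |Specimen| : 272102008 |Weight|"
```

Generating the packaged default registry reconstruction and tallying it:

```r
reg <- generateRegistry(defaultProfile(seed = 0), eq, g)
registryStats(reg, eq, g)
#> Registry statistics
#>   templates: 488 (467 observations, 21 procedures)
#>   observations: 450 generic-mapped, 17 specific
#>   distinct generic elements: 53 (28 staging/grading/classification, 15 marker, 9 core generic)
#>   distinct locator organs: 20
#>   SNOMED coverage of generic elements: 100.0%
```

488 templates reduce to 53 distinct generic elements: the decomposer
recovers each element from the template names and value sets alone, the 17
organ/disease-specific templates stay specific (their value sets differ
across contexts), and the 21 procedures are classified as such. See the
vignette (`vignettes/generic-ap-observations.Rmd`) for the model, the
modelling decisions, and what the synthetic registry does and does not
emulate.

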