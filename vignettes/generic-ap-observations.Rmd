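---
title: "A generic reference terminology model for anatomic pathology observations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A generic reference terminology model for anatomic pathology observations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apterms)
```

## The problem

Interface terminologies for structured pathology reporting are built for
fast data entry: every reportable feature is *precoordinated* into one
enumerated term per organ and disease, such as
`Breast-In situ neoplasm-Lesion size, largest dimension`. That is quick to
deploy but scales badly — hundreds of templates that differ only in their
organ/problem context, with no machine-readable relationships between them.

The alternative is *postcoordination*: a small reference model in which any
anatomic-pathology observation

* occurs in a **context** of location (locator organ), pathological problem
  (problem organizer, e.g. invasive vs. non-invasive tumor) and observation
  method, and
* consists of a **target of observation** (specimen, lesion, margin,
  nucleus, ...), a **property of observation** (diameter, weight, grade,
  colour, ...) and additional **qualifiers** (laterality, invasiveness,
  "largest", ...), optionally completed by a value.

`apterms` implements this model end to end: the ontology with its
permissible value sets, an expression composer/validator, serializers, a
decomposer from precoordinated names back to generic expressions, the
genericity criterion, registry statistics, and a synthetic registry
generator that makes the whole pipeline testable without any terminology
download.

## The ontology and the "descendants included" rule

Concepts are identified by `(namespace, code)`: SNOMED CT concept ids where
a mapping exists, package-local tokens otherwise. Four relationship types
are stored: `IS_A`, `PART_OF`, `HAS_TARGET` (property to target) and
`IS_QUALIFIER_OF` (qualifier to observation). The target-side reading
`IS_TARGET_OF` is exposed only as the inverse view of `HAS_TARGET`, never
stored, so there is one canonical edge direction. The `IS_A` and `PART_OF`
subgraphs are kept acyclic: every mutation re-checks reachability and a
cycle-closing edge is refused with the offending path named.

Permissible value sets are defined as "these concepts, their descendants
included". Without a SNOMED CT release there are no real descendant sets,
so the packaged tables are made executable by a modelling decision: the
printed axis annotation of each row (e.g. *(qualifier value)*) becomes an
`IS_A` edge to a local axis-root concept, and `isPermissible(g, x, root)`
tests whether `root` lies in the reflexive-transitive `IS_A` closure of
`x`. Users extending the graph get the intended semantics for free: any
concept registered `IS_A` below `Lesion` is a permissible target.

Two transcription details are worth noting. Codes the source prints in
parentheses (`NeighborhoodRelationship`, `(Treatment)Effect`) are loaded
with `approximate = TRUE`; they still count as mapped for coverage, the
flag merely preserves the reservation. And the qualifier row
`abnormalStructure` carries the same SNOMED code as the target `Lesion`
(49755003); since concept identity is `(namespace, code)`, both rows
resolve to one graph node — the same real-world concept playing two roles.
The property table's printed header is corrupted in the source ("...Axis)
Area"); the transcription treats `Area 42798000 (qualifier value)` as the
first data row, giving 22 property rows.

## Expressions, canonical form, subsumption

`composeObservation()` validates every slot against the role roots (targets
from the target table, properties from the property table, qualifiers from
the qualifier table plus the observation methods) and reports *all*
violations in one aggregated constraint error. Qualifiers are canonicalized
by sorting on `(namespace, code)` and de-duplicating, so equality is
order-insensitive; the source gives no qualifier ordering, which makes the
sorted form the natural canonical one. The observation method lives in the
context rather than the general qualifier list, mirroring how the model
phrases the worked example (a diameter "observed by microscopic
investigation" of a lesion in the breast).

A context-free expression is legal: generic terms exist independent of
organ and problem, the "always in a context" requirement being satisfied at
document level where the locator and problem organizers live. Subsumption
(`subsumes(a, b, g)`) therefore treats an absent slot in the subsumer as
most general — standard postcoordination semantics. `a` subsumes `b` when
each filled slot of `a` is an `IS_A` ancestor-or-self of `b`'s slot and
`a`'s qualifier set is a subset of `b`'s under `IS_A` matching; the
relation is a preorder (reflexive, transitive). Values are deliberately not
compared: value-set contents are out of scope for the model.

The special attributes (`nearest`, `biggest`, `most`, `least`, `smallest`,
plus `largest` from the worked example) are an open local enumeration under
the `specialAttributes` qualifier — the source's "etc." is read as
extensibility, so users can register further tokens.

## Serializations

Three writers share one canonical expression model, and each is paired with
a reader that resolves codes against the graph and re-composes (hence
re-validates) the expression, so every round trip preserves canonical
equality:

* **Compositional-grammar strings** (`toSCG()`): the target is the focus
  concept, the property the first (bare) refinement, then `qual =`, `loc =`,
  `prob =`, `method =`, `val =` pairs in fixed order. Local concepts carry a
  reserved `ap:` prefix. A quantity renders as `val = #3.5 mm`. Because a
  property is mandatory, the minimal rendering is
  `123038009 |Specimen| : 272102008 |Weight|` — the refinement block is
  present whenever the expression is complete.
* **JSON** (`expressionToJSON()`): fixed key order, absent slots `null`.
* **HL7-template-style XML** (`writeExpressionXML()`): an artifact-defined
  dialect with CDA-compatible conventions (no CDA conformance claimed) —
  lower-camel element names, `code/@code` with `codeSystem` fixed to the
  SNOMED CT OID 2.16.840.1.113883.6.96, local concepts under a reserved
  branch (2.25.42424242.1). The property element carries
  `relationship="HAS-TARGET"`, qualifier and method elements
  `relationship="IS-QUALIFIER-OF"`. Output is byte-deterministic (fixed
  attribute order, fixed namespace declaration, two-space indent) and every
  emitted document validates against the shipped XSD
  (`observationSchema()`).

Registries travel as tab-delimited text with `|`-separated value-set
members — tabs and pipes survive the commas that routinely occur inside
display names. Malformed rows (bad OID, empty name, unknown category) are
never silently dropped; they are collected into the `skipped` attribute.

## Decomposition and the genericity criterion

`parseName()` splits `Organ-Problem-Element` names on `-`, but only when
the first segment is a known organ token: the organ lexicon disambiguates
hyphens inside element names (`Ki-67`, `BI-RADS category`), and commas and
spaces are never delimiters. `decomposeTerm()` then matches the element
against the recipe catalog and the 17-row equivalence table,
longest-pattern-first and case-insensitively (patterns are matched on token
boundaries, so `pT` does not fire inside `receptor`); equal-length ties
resolve lexicographically with a warning. A match yields the canonical
generic expression — recipe target, property, qualifiers and method, with
locator and problem resolved from the parsed context. Unmatched
observations are verdict `specific`, which is a result, not an error;
procedure-category templates are classified `procedure` and not modelled
further (the model defers procedure semantics).

The genericity criterion is value-set uniqueness: an element is generic
when every occurrence across all `(organ, problem)` contexts carries the
same value set, compared order-insensitively. A single occurrence is
vacuously generic by default; `strictSingle = TRUE` inverts that policy for
users who prefer to treat one-off elements as specific.

`registryStats()` tallies the breakdown. Its coverage figure uses distinct
generic elements as the denominator (coverage is a statement about the
generic inventory, not about templates) and counts an element as mapped
when its property concept carries a SNOMED code, approximate mappings
included. On the packaged reconstruction every recipe property is coded, so
the reported coverage is 100%; the published two-thirds figure has an
ambiguous denominator (it may include value-set contents, which this
package does not model) and is therefore not reproduced as a target. The
standalone `snomedCoverage()` de-duplicates by `(namespace, code,
designation)`, so repeated rows do not bias the figure while distinct table
rows that share a code (the `abnormalStructure`/`Lesion` case) still count
as the two printed rows.

## The synthetic registry generator

`generateRegistry()` emulates a precoordinated interface-terminology
registry from a composition profile. The packaged default reconstructs the
published breakdown: 53 distinct generic elements — 9 core-generic recipes
(Diameter, Distance, Extent, Focality, Growth pattern, Integrity,
Involvement, Number, Weight), 28 staging/grading/classification recipes, 15
marker recipes, and one unclassified-generic slot (Treatment Effect),
since the three named families alone account for only 52 of the 53 — plus
17 organ/disease-specific templates over 6 elements and 21 procedure
templates. Expansion multiplicities are profile data: core recipes over 20
contexts each, staging over 8, markers over 3, the unclassified slot over
1, giving 450 generic-mapped observation templates, 467 observations and
488 templates in total across 20 organs.

Everything the source does not enumerate is an explicit reconstruction and
lives in the profile: the 20 organ tokens, the per-family multiplicities,
the staging/grading/classification and marker family members (parameterized
as pT/pN/pM-style schemes and named markers rather than transcribed), the
specific-element names and the procedure names. The generator is
deterministic for a fixed seed; context draws use the seed, while the
family counts are seed-invariant by construction. Core recipes cycle
through every organ (problems alternating), so all 20 organs always appear.

Two properties make the generator a genuine test instrument rather than a
fixture: generic-family templates carry their recipe's context-invariant
value set while each specific element gets exactly one perturbed context
(one extra member — the minimal violation of the uniqueness criterion), so
the decomposer and classifier must recover the composition from names and
value sets alone; and the generator→decomposer identity (every
generic-family row decomposes to exactly its source recipe) is asserted
row-by-row in the tests via a sidecar attribute the decomposer never reads.

What passing these tests shows — and what it does not: the pipeline
reproduces the published breakdown on a registry *shaped* like the real
one. The synthetic names are cleaner than real interface terms (no
spelling variants, no ad-hoc abbreviations, no multi-hyphen context
corner cases beyond those modelled), value sets are short token lists, and
the real spreadsheet is never ingested. Results on real registries will
degrade exactly where the name grammar or the pattern table is too clean;
both are configurable (`nameGrammar()`, the packaged TSVs) for that reason.

## Numerical and degenerate-input choices

* Closure queries are breadth-first over the edge table; returned key sets
  are radix-sorted, so results are deterministic across locales.
* Duplicate edge insertion is idempotent (table loaders re-read shared
  parents); duplicate concept registration on the same key is a no-op.
* Empty profiles yield empty registries; empty registries yield all-zero
  reports. Coverage of an empty concept collection is an error rather than
  a silent 0/0.
* Quantities must be finite with a nonempty unit; exactly one of coded
  value or quantity is populated.
* The worked example cites a template OID under a branch that differs from
  every other printed OID in one digit (49376 vs. 19376); the packaged
  equivalence table records the discrepancy in a note column and corrects
  nothing.
* `Focality` appears both as a generic element and as an uncoded qualifier;
  it is modelled as a qualifier with an equivalence-row alias whose recipe
  uses it as such.

## Problem sizes used in the checks

The packaged tests run the full default reconstruction (488 templates),
closure-versus-oracle comparisons on random DAGs of up to 50 nodes against
an unmemoized path-enumerating DFS, subsumption against a slot-wise oracle
on random expression pairs, and 100 random expressions through each of the
JSON/XML/SCG round trips. `scripts/acceptance.R` regenerates the default
registry from scratch and re-derives every breakdown figure at run time.

## Known limitations

* No SNOMED CT release ingestion, no expression-constraint evaluation, no
  description-logic classification beyond the four relationship types.
* Value-set *contents* are tokens, not modelled concepts; the genericity
  criterion compares them as opaque sets.
* Procedures are a classification category only.
* The XML dialect is this package's own; it is CDA-flavoured but not a
  conformant CDA entry.
* The default profile is a reconstruction of a published breakdown, not the
  published registry itself.
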