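#' @import methods
NULL

#' Reference to a terminology concept
#'
#' A `ConceptRef` identifies one concept, either by its SNOMED CT concept id
#' (`namespace = "snomed"`) or by a package-local token (`namespace =
#' "local"`) for elements the source tables leave uncoded. The `axis` records
#' the SNOMED CT top-level hierarchy printed next to the code (qualifier
#' value, attribute, body structure, ...); `approximate` flags codes the
#' source prints in parentheses, i.e. mappings offered with reservation.
#'
#' @slot code character(1); digits for SNOMED concepts, a slug token for
#'   local concepts.
#' @slot namespace character(1); `"snomed"` or `"local"`.
#' @slot designation character(1); human-readable label, never empty.
#' @slot axis character(1) or `NA`; SNOMED CT axis annotation.
#' @slot approximate logical(1); `TRUE` when the mapping is tentative.
#'
#' @export
setClass("ConceptRef",
  representation(
    code = "character",
    namespace = "character",
    designation = "character",
    axis = "character",
    approximate = "logical"
  ),
  prototype(axis = NA_character_, approximate = FALSE)
)

.validAxes <- c(
  "qualifier value", "attribute", "morphologic abnormality", "body structure",
  "cell structure", "specimen", "disorder", "procedure", "observable entity"
)

setValidity("ConceptRef", function(object) {
  msgs <- character()
  if (length(object@code) != 1L || !nzchar(object@code))
    msgs <- c(msgs, "code must be a nonempty string")
  if (length(object@namespace) != 1L || !object@namespace %in% c("snomed", "local"))
    msgs <- c(msgs, "namespace must be 'snomed' or 'local'")
  if (identical(object@namespace, "snomed") && !grepl("^[0-9]+$", object@code))
    msgs <- c(msgs, sprintf("snomed code must be all digits, got '%s'", object@code))
  if (length(object@designation) != 1L || is.na(object@designation) ||
      !nzchar(object@designation))
    msgs <- c(msgs, "designation must be nonempty")
  if (length(object@designation) == 1L && grepl("|", object@designation, fixed = TRUE))
    msgs <- c(msgs, "designation must not contain '|'")
  if (length(object@axis) != 1L || (!is.na(object@axis) && !object@axis %in% .validAxes))
    msgs <- c(msgs, sprintf("unknown axis '%s'", object@axis))
  if (length(object@approximate) != 1L || is.na(object@approximate))
    msgs <- c(msgs, "approximate must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' The four relationship types of the reference model
#'
#' Stored relationship types are `IS_A`, `PART_OF`, `HAS_TARGET` and
#' `IS_QUALIFIER_OF`. The target-side view `IS_TARGET_OF` is never stored; it
#' is exposed only as the inverse reading of `HAS_TARGET` (see
#' [relationTable()]).
#'
#' @export
relationshipTypes <- function() c("IS_A", "PART_OF", "HAS_TARGET", "IS_QUALIFIER_OF")

#' Ontology graph of concepts and typed relationships
#'
#' Holds registered concepts and directed edges `(child, type, parent)` for
#' the four relationship types of the reference model. The `IS_A` and
#' `PART_OF` subgraphs are kept acyclic by construction. The `roles` list
#' names, per expression role (target, property, qualifier, method, locator,
#' problem), the concept keys that act as permissible-value roots:
#' a concept fills a role when some root is among its `IS_A` ancestors
#' ("descendants included").
#'
#' @slot concepts data.frame with columns `key`, `code`, `namespace`,
#'   `designation`, `axis`, `approximate`; one row per concept,
#'   `key = namespace:code` unique.
#' @slot edges data.frame with columns `child`, `type`, `parent` (concept
#'   keys).
#' @slot roles named list of character vectors of concept keys.
#'
#' @export
setClass("OntologyGraph",
  representation(concepts = "data.frame", edges = "data.frame", roles = "list")
)

setValidity("OntologyGraph", function(object) {
  msgs <- character()
  cn <- object@concepts
  en <- object@edges
  if (!all(c("key", "code", "namespace", "designation", "axis", "approximate")
           %in% names(cn)))
    msgs <- c(msgs, "concepts table lacks required columns")
  if (anyDuplicated(cn$key))
    msgs <- c(msgs, "duplicate (namespace, code) concept keys")
  if (!all(c("child", "type", "parent") %in% names(en)))
    msgs <- c(msgs, "edges table lacks required columns")
  if (nrow(en)) {
    if (!all(en$type %in% relationshipTypes()))
      msgs <- c(msgs, "unknown relationship type in edges")
    if (!all(c(en$child, en$parent) %in% cn$key))
      msgs <- c(msgs, "edge endpoint not registered as a concept")
    for (tp in c("IS_A", "PART_OF")) {
      if (.hasCycle(en[en$type == tp, , drop = FALSE]))
        msgs <- c(msgs, sprintf("%s subgraph is cyclic", tp))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Value carried by an observation
#'
#' Exactly one of a coded value (a [ConceptRef-class]) or a physical quantity
#' (finite decimal magnitude plus a UCUM-style unit token) is populated.
#'
#' @slot coded a [ConceptRef-class] or `NULL`.
#' @slot magnitude numeric(1) or empty.
#' @slot unit character(1) or empty.
#'
#' @export
setClass("ObservationValue",
  representation(coded = "ANY", magnitude = "numeric", unit = "character"),
  prototype(coded = NULL, magnitude = numeric(0), unit = character(0))
)

setValidity("ObservationValue", function(object) {
  hasCoded <- !is.null(object@coded)
  hasQty <- length(object@magnitude) == 1L
  if (hasCoded && !is(object@coded, "ConceptRef"))
    return("coded value must be a ConceptRef")
  if (hasCoded == hasQty)
    return("exactly one of coded value or quantity must be populated")
  if (hasQty) {
    if (!is.finite(object@magnitude)) return("quantity magnitude must be finite")
    if (length(object@unit) != 1L || !nzchar(object@unit))
      return("quantity requires a nonempty unit")
  }
  TRUE
})

#' Observation context: locator, problem organizer, observation method
#'
#' Every anatomic-pathology observation occurs in a context of location,
#' pathological problem and observation method. At the level of a single
#' generic expression each element is optional: generic terms exist
#' context-free, the context being supplied by the surrounding document.
#'
#' @slot locator [ConceptRef-class] or `NULL`; organ / body site.
#' @slot problem [ConceptRef-class] or `NULL`; pathological problem
#'   organizer (e.g. invasive tumor, non-invasive tumor).
#' @slot method [ConceptRef-class] or `NULL`; observation method qualifier
#'   (e.g. ObservedByMicroscopicInvestigation).
#'
#' @export
setClass("Context",
  representation(locator = "ANY", problem = "ANY", method = "ANY"),
  prototype(locator = NULL, problem = NULL, method = NULL)
)

setValidity("Context", function(object) {
  for (s in c("locator", "problem", "method")) {
    v <- slot(object, s)
    if (!is.null(v) && !is(v, "ConceptRef"))
      return(sprintf("%s must be a ConceptRef or NULL", s))
  }
  TRUE
})

#' Postcoordinated generic observation expression
#'
#' The central expression type: context + exactly one target + exactly one
#' property + a canonicalized set of qualifiers + optional value. Instances
#' are built with [composeObservation()], which validates every role against
#' the ontology's permissible-value roots and canonicalizes the qualifier
#' order; do not construct with `new()` directly.
#'
#' @slot context a [Context-class].
#' @slot target [ConceptRef-class]; the entity observed.
#' @slot property [ConceptRef-class]; the attribute observed.
#' @slot qualifiers list of [ConceptRef-class], sorted by (namespace, code),
#'   no duplicates.
#' @slot value [ObservationValue-class] or `NULL`.
#' @slot graphId character(1); structural signature of the graph the
#'   expression was validated against.
#'
#' @export
setClass("GenericObservation",
  representation(
    context = "Context",
    target = "ConceptRef",
    property = "ConceptRef",
    qualifiers = "list",
    value = "ANY",
    graphId = "character"
  ),
  prototype(qualifiers = list(), value = NULL, graphId = NA_character_)
)

setValidity("GenericObservation", function(object) {
  msgs <- character()
  if (!all(vapply(object@qualifiers, is, logical(1), class2 = "ConceptRef")))
    msgs <- c(msgs, "qualifiers must all be ConceptRef")
  keys <- vapply(object@qualifiers, conceptKey, character(1))
  if (anyDuplicated(keys)) msgs <- c(msgs, "duplicate qualifiers")
  if (length(keys) > 1L && is.unsorted(keys))
    msgs <- c(msgs, "qualifiers must be in canonical (namespace, code) order")
  if (!is.null(object@value) && !is(object@value, "ObservationValue"))
    msgs <- c(msgs, "value must be an ObservationValue or NULL")
  if (length(msgs)) msgs else TRUE
})

#' One precoordinated interface-terminology term
#'
#' A single row of an interface-terminology registry: a template OID, a
#' display name (possibly carrying `Organ-Problem-Element` context in the
#' name), the parsed context tokens, a category (observation or procedure)
#' and the enumerated value set (empty for quantitative terms).
#'
#' @slot oid character(1); dotted-decimal template OID.
#' @slot name character(1); display name.
#' @slot organ character(1) or `NA`.
#' @slot problem character(1) or `NA`.
#' @slot category character(1); `"observation"` or `"procedure"`.
#' @slot value_set character vector of value tokens, possibly empty.
#'
#' @export
setClass("PrecoordinatedTerm",
  representation(
    oid = "character", name = "character", organ = "character",
    problem = "character", category = "character", value_set = "character"
  ),
  prototype(organ = NA_character_, problem = NA_character_,
            category = "observation", value_set = character(0))
)

setValidity("PrecoordinatedTerm", function(object) {
  msgs <- character()
  if (!isValidOID(object@oid))
    msgs <- c(msgs, sprintf("malformed OID '%s'", object@oid))
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "name must be nonempty")
  if (!object@category %in% c("observation", "procedure"))
    msgs <- c(msgs, "category must be 'observation' or 'procedure'")
  if (length(msgs)) msgs else TRUE
})

#' Equivalence table from interface element names to generic elements
#'
#' Wraps the packaged 17-row equivalence table (interface element-name
#' patterns to generic element designations, with the expression recipe each
#' implies) together with the expanded recipe catalog used by the default
#' registry reconstruction (53 generic elements across the core,
#' staging/grading/classification, marker and unclassified-generic families).
#'
#' @slot rows data.frame; the 17 packaged equivalence rows.
#' @slot recipes data.frame; the recipe catalog (one row per distinct
#'   generic element).
#'
#' @export
setClass("EquivalenceTable",
  representation(rows = "data.frame", recipes = "data.frame")
)

setValidity("EquivalenceTable", function(object) {
  msgs <- character()
  if (nrow(object@rows) != 17L)
    msgs <- c(msgs, sprintf("equivalence table must have exactly 17 rows, got %d",
                            nrow(object@rows)))
  if (anyDuplicated(object@rows$element))
    msgs <- c(msgs, "generic element designations must be unique")
  if (nrow(object@recipes) && anyDuplicated(object@recipes$designation))
    msgs <- c(msgs, "recipe designations must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Result of decomposing one precoordinated term
#'
#' @slot verdict character(1); `"generic"`, `"specific"` or `"procedure"`.
#' @slot expression [GenericObservation-class] or `NULL`; present iff the
#'   verdict is generic.
#' @slot matchedGenericElement character(1) or `NA`; designation of the
#'   recovered generic element.
#' @slot family character(1) or `NA`; family of the matched element.
#' @slot unmatchedReason character(1) or `NA`.
#'
#' @export
setClass("DecompositionResult",
  representation(
    verdict = "character", expression = "ANY",
    matchedGenericElement = "character", family = "character",
    unmatchedReason = "character"
  ),
  prototype(expression = NULL, matchedGenericElement = NA_character_,
            family = NA_character_, unmatchedReason = NA_character_)
)

setValidity("DecompositionResult", function(object) {
  if (!object@verdict %in% c("generic", "specific", "procedure"))
    return("verdict must be generic, specific or procedure")
  if (identical(object@verdict, "generic") && is.null(object@expression))
    return("generic verdict requires an expression")
  if (!identical(object@verdict, "generic") && !is.null(object@expression))
    return("expression only allowed for generic verdicts")
  TRUE
})

#' Registry breakdown statistics
#'
#' Tallies produced by [registryStats()]: template counts by category,
#' distinct generic elements recovered by family, distinct locator organs
#' and the SNOMED mapping coverage of the recovered generic elements.
#'
#' @slot totalTemplates,observations,procedures numeric(1) template counts.
#' @slot genericMapped,specificTerms numeric(1); observation templates that
#'   mapped to a generic element / were left specific.
#' @slot genericElements numeric(1); distinct generic elements recovered.
#' @slot stagingGradingClassificationTerms,markerTerms,coreGenericTerms
#'   numeric(1); distinct generic elements per family.
#' @slot organs numeric(1); distinct locator organ tokens.
#' @slot coveragePercent numeric(1); percent of distinct generic elements
#'   whose property concept carries a SNOMED code.
#' @slot skipped data.frame of malformed entries that were not tallied.
#'
#' @export
setClass("StatsReport",
  representation(
    totalTemplates = "numeric", observations = "numeric", procedures = "numeric",
    genericMapped = "numeric", specificTerms = "numeric",
    genericElements = "numeric",
    stagingGradingClassificationTerms = "numeric", markerTerms = "numeric",
    coreGenericTerms = "numeric", organs = "numeric",
    coveragePercent = "numeric", skipped = "data.frame"
  )
)

setValidity("StatsReport", function(object) {
  msgs <- character()
  if (object@observations + object@procedures != object@totalTemplates)
    msgs <- c(msgs, "observations + procedures must equal totalTemplates")
  if (object@genericMapped + object@specificTerms != object@observations)
    msgs <- c(msgs, "generic-mapped + specific must equal observations")
  fam <- object@stagingGradingClassificationTerms + object@markerTerms +
    object@coreGenericTerms
  if (fam > object@genericElements)
    msgs <- c(msgs, "family tallies exceed distinct generic elements")
  if (object@coveragePercent < 0 || object@coveragePercent > 100)
    msgs <- c(msgs, "coveragePercent must lie in [0, 100]")
  if (length(msgs)) msgs else TRUE
})

#' Composition profile for synthetic registry generation
#'
#' Describes the composition of a synthetic precoordinated registry: the
#' organ and problem lexicons, how many `(organ, problem)` contexts each
#' generic-element family is expanded over, the specific-term elements with
#' their occurrence multiplicities, the procedure template names, the OID
#' allocation branch and the random seed. The packaged default
#' ([defaultProfile()]) reconstructs the published registry breakdown.
#'
#' @slot organs character; organ tokens (a reconstruction, the source lists
#'   none).
#' @slot problems character; problem tokens used in template names.
#' @slot contextsPerFamily named numeric; contexts per recipe for the
#'   families `core_generic`, `staging_grading_classification`, `marker`,
#'   `unclassified_generic`.
#' @slot specificElements character; element names of organ/disease-specific
#'   templates.
#' @slot specificOccurrences numeric; per-element context multiplicities.
#' @slot specificValueSet character; base value set that gets perturbed in
#'   one context per specific element.
#' @slot procedureNames character; procedure template names.
#' @slot oidBranch character(1); reserved dotted-decimal branch for
#'   sequential OID allocation.
#' @slot seed numeric(1).
#'
#' @export
setClass("CompositionProfile",
  representation(
    organs = "character", problems = "character",
    contextsPerFamily = "numeric",
    specificElements = "character", specificOccurrences = "numeric",
    specificValueSet = "character", procedureNames = "character",
    oidBranch = "character", seed = "numeric"
  )
)

setValidity("CompositionProfile", function(object) {
  msgs <- character()
  if (any(object@contextsPerFamily < 0) || any(object@specificOccurrences < 0))
    msgs <- c(msgs, "counts must be non-negative")
  if (length(object@specificOccurrences) != length(object@specificElements))
    msgs <- c(msgs, "one occurrence count per specific element required")
  ctxBearing <- sum(object@contextsPerFamily) + sum(object@specificOccurrences)
  if (ctxBearing > 0 && length(object@organs) == 0L)
    msgs <- c(msgs, "organ list must be nonempty when context-bearing counts are positive")
  if (ctxBearing > 0 && length(object@problems) == 0L)
    msgs <- c(msgs, "problem list must be nonempty when context-bearing counts are positive")
  if (!isValidOID(object@oidBranch))
    msgs <- c(msgs, "oidBranch must be a dotted-decimal OID")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed must be a single integer")
  if (length(msgs)) msgs else TRUE
})

#' Delimited registry dialect
#'
#' Column layout and separators for reading/writing precoordinated-term
#' registries as delimited text: header row required, fixed column order
#' (oid, name, organ, problem, category, value_set), tab delimiter and `|`
#' value-set member separator by default so that commas inside display names
#' survive.
#'
#' @slot delimiter character(1) field separator.
#' @slot vsSep character(1) value-set member separator.
#' @slot encoding character(1).
#'
#' @export
setClass("PathlexDialect",
  representation(delimiter = "character", vsSep = "character", encoding = "character"),
  prototype(delimiter = "\t", vsSep = "|", encoding = "UTF-8")
)
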