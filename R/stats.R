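#' Registry breakdown statistics
#'
#' Runs [decomposeTerm()] on every registry entry and tallies the breakdown:
#' template counts by category, observation templates mapped to a generic
#' element vs. left specific, distinct generic elements recovered (overall
#' and per family), distinct locator organs across all template names, and
#' the SNOMED mapping coverage of the recovered generic elements (a generic
#' element counts as mapped when its property concept carries a SNOMED code,
#' approximate mappings included; the denominator is distinct generic
#' elements, not templates).
#'
#' @param registry registry data.frame ([readRegistry()] /
#'   [generateRegistry()]).
#' @param eq an [EquivalenceTable-class].
#' @param graph the reference [OntologyGraph-class].
#' @param grammar a [nameGrammar()].
#' @return a [StatsReport-class].
#' @examples
#' \donttest{
#' g <- buildReferenceOntology(); eq <- loadEquivalenceTable()
#' registryStats(generateRegistry(defaultProfile(), eq, g), eq, g)
#' }
#' @export
registryStats <- function(registry, eq, graph, grammar = nameGrammar()) {
  skipped <- attr(registry, "skipped")
  if (is.null(skipped))
    skipped <- data.frame(row = integer(), oid = character(),
                          reason = character(), stringsAsFactors = FALSE)
  if (!nrow(registry)) {
    return(new("StatsReport", totalTemplates = 0, observations = 0,
               procedures = 0, genericMapped = 0, specificTerms = 0,
               genericElements = 0, stagingGradingClassificationTerms = 0,
               markerTerms = 0, coreGenericTerms = 0, organs = 0,
               coveragePercent = 0, skipped = skipped))
  }
  dec <- decomposeRegistry(registry, eq, graph, grammar)
  generic <- dec[dec$verdict == "generic", , drop = FALSE]
  elements <- unique(generic$element)
  famOf <- generic$family[match(elements, generic$element)]

  organs <- unique(stats::na.omit(vapply(registry$name, function(nm)
    parseName(nm, grammar)$organ, character(1), USE.NAMES = FALSE)))

  # coverage: distinct generic elements whose property concept is SNOMED-coded
  covered <- 0L
  for (el in elements) {
    i <- match(el, eq@recipes$designation)
    propName <- if (!is.na(i)) eq@recipes$property[i] else
      eq@rows$property[match(el, eq@rows$element)]
    pc <- tryCatch(resolveConcept(graph, propName), aptermsError = function(e) NULL)
    if (!is.null(pc) && identical(pc@namespace, "snomed")) covered <- covered + 1L
  }
  coverage <- if (length(elements)) round(100 * covered / length(elements), 1) else 0

  new("StatsReport",
      totalTemplates = nrow(registry),
      observations = sum(dec$verdict != "procedure"),
      procedures = sum(dec$verdict == "procedure"),
      genericMapped = sum(dec$verdict == "generic"),
      specificTerms = sum(dec$verdict == "specific"),
      genericElements = length(elements),
      stagingGradingClassificationTerms =
        sum(famOf == "staging_grading_classification"),
      markerTerms = sum(famOf == "marker"),
      coreGenericTerms = sum(famOf == "core_generic"),
      organs = length(organs),
      coveragePercent = coverage,
      skipped = skipped)
}

#' Convert a stats report to a plain list
#'
#' @param report a [StatsReport-class].
#' @return named list of the tallies (for JSON output).
#' @export
statsAsList <- function(report) {
  list(
    total_templates = report@totalTemplates,
    observations = report@observations,
    procedures = report@procedures,
    generic_mapped = report@genericMapped,
    specific_terms = report@specificTerms,
    generic_elements = report@genericElements,
    staging_grading_classification_terms =
      report@stagingGradingClassificationTerms,
    marker_terms = report@markerTerms,
    core_generic_terms = report@coreGenericTerms,
    organs = report@organs,
    coverage_percent = report@coveragePercent,
    skipped = nrow(report@skipped)
  )
}

setMethod("show", "StatsReport", function(object) {
  cat("Registry statistics\n")
  cat(sprintf("  templates: %d (%d observations, %d procedures)\n",
              object@totalTemplates, object@observations, object@procedures))
  cat(sprintf("  observations: %d generic-mapped, %d specific\n",
              object@genericMapped, object@specificTerms))
  cat(sprintf("  distinct generic elements: %d (%d staging/grading/classification, %d marker, %d core generic)\n",
              object@genericElements, object@stagingGradingClassificationTerms,
              object@markerTerms, object@coreGenericTerms))
  cat(sprintf("  distinct locator organs: %d\n", object@organs))
  cat(sprintf("  SNOMED coverage of generic elements: %.1f%%\n",
              object@coveragePercent))
  if (nrow(object@skipped))
    cat(sprintf("  skipped entries: %d\n", nrow(object@skipped)))
})
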