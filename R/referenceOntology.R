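#' Path to a packaged data file
#' @param file file name under the package's `extdata` directory.
#' @keywords internal
aptermsFile <- function(file) {
  p <- system.file("extdata", file, package = "apterms")
  if (!nzchar(p)) apAbort(sprintf("packaged file not found: %s", file), "apConfigError")
  p
}

.readTSV <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                    comment.char = "", ...)
}

#' Load a packaged permissible-value table
#'
#' Reads one of the packaged value-set transcriptions (`targets.tsv`,
#' `properties.tsv`, `qualifiers.tsv`): columns designation, SNOMED code
#' (may be empty), axis, approximate flag. Rows without a code become local
#' concepts. The loader is bit-exact on the packaged files: one
#' [ConceptRef-class] per row, in file order.
#'
#' @param path path to the table, or the bare name of a packaged one.
#' @return list of [ConceptRef-class].
#' @examples
#' length(loadValueSetTable("targets.tsv"))
#' @export
loadValueSetTable <- function(path) {
  if (!file.exists(path)) path <- aptermsFile(path)
  df <- .readTSV(path, colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    code <- df$code[i]
    conceptRef(
      code = if (nzchar(code)) code else NULL,
      designation = df$designation[i],
      namespace = if (nzchar(code)) "snomed" else "local",
      axis = if (nzchar(df$axis[i])) df$axis[i] else NA_character_,
      approximate = identical(toupper(df$approximate[i]), "TRUE")
    )
  })
}

#' The default organ lexicon
#'
#' Twenty organ tokens used by the default composition profile and by the
#' name grammar to recognize context-bearing template names. The token list
#' is a reconstruction: the source states that twenty organs exist but does
#' not enumerate them.
#'
#' @return character vector of organ tokens.
#' @export
defaultOrgans <- function() {
  .readTSV(aptermsFile("organs.tsv"))$organ
}

#' Problem-token lexicon
#'
#' Maps problem tokens as they appear in template names (e.g. "In situ
#' neoplasm") to canonical problem-organizer designations (e.g.
#' "non-invasive tumor").
#'
#' @return data.frame with columns `token`, `problem`.
#' @export
problemLexicon <- function() {
  .readTSV(aptermsFile("problems.tsv"))
}

.methodConcepts <- c("ObservedByMicroscopicInvestigation",
                     "ObservedByMacroscopicInvestigation",
                     "ObservedByMolecularInvestigation")

.specialAttributeTokens <- c("nearest", "biggest", "most", "least",
                             "smallest", "largest")

localRef <- function(designation, axis = NA_character_)
  conceptRef(designation = designation, namespace = "local", axis = axis)

#' Build the packaged reference ontology
#'
#' Assembles the ontology graph behind the generic observation model:
#'
#' * a local root concept per SNOMED CT axis; every coded table row gets an
#'   `IS_A` edge to its axis root, which makes the "descendants included"
#'   rule executable without a SNOMED release;
#' * the packaged target, property and qualifier tables as concepts (role
#'   roots for expression validation);
#' * local organ concepts (`IS_A` the body-structure axis root), the
#'   pathological-problem organizers, the observation-method qualifiers and
#'   the open special-attribute enumeration (nearest, biggest, most, least,
#'   smallest, largest) under the `specialAttributes` qualifier;
#' * `HAS_TARGET` edges from each equivalence-recipe property to its target
#'   and `IS_QUALIFIER_OF` edges from each qualifier root to the local
#'   AP-observation concept;
#' * a handful of `PART_OF` edges along the anatomic containment chain
#'   (nucleolus - nucleus - cell - tissue - organ; margin - specimen).
#'
#' @return an [OntologyGraph-class] with role roots populated.
#' @examples
#' g <- buildReferenceOntology()
#' isPermissible(g, resolveConcept(g, "Breast"), "local:body-structure")
#' @export
buildReferenceOntology <- function() {
  g <- ontologyGraph()

  axisRoots <- stats::setNames(
    lapply(.validAxes, function(a) localRef(a)), .validAxes)
  g <- addConcept(g, unname(axisRoots))

  obsRoot <- localRef("AP observation")
  g <- addConcept(g, obsRoot)

  tabs <- list(target = loadValueSetTable("targets.tsv"),
               property = loadValueSetTable("properties.tsv"),
               qualifier = loadValueSetTable("qualifiers.tsv"))
  for (nm in names(tabs)) {
    for (cc in tabs[[nm]]) {
      g <- addConcept(g, cc)
      if (!is.na(cc@axis))
        g <- addRelation(g, cc, "IS_A", axisRoots[[cc@axis]])
    }
  }

  # qualifier roots hang off the observation root via IS-QUALIFIER-OF
  for (cc in tabs$qualifier)
    g <- addRelation(g, cc, "IS_QUALIFIER_OF", obsRoot)

  # open special-attribute enumeration
  special <- conceptKey(localRef("specialAttributes"))
  for (tok in .specialAttributeTokens) {
    cc <- localRef(tok)
    g <- addConcept(g, cc)
    g <- addRelation(g, cc, "IS_A", special)
  }

  # observation methods
  methodRoot <- localRef("ObservationMethod")
  g <- addConcept(g, methodRoot)
  for (m in .methodConcepts) {
    cc <- localRef(m)
    g <- addConcept(g, cc)
    g <- addRelation(g, cc, "IS_A", methodRoot)
  }

  # problem organizers
  problemRoot <- localRef("PathologicalProblem")
  g <- addConcept(g, problemRoot)
  for (p in unique(problemLexicon()$problem)) {
    cc <- localRef(p)
    g <- addConcept(g, cc)
    g <- addRelation(g, cc, "IS_A", problemRoot)
  }

  # organs as local body-structure concepts
  bodyRoot <- axisRoots[["body structure"]]
  for (o in defaultOrgans()) {
    cc <- localRef(o, axis = "body structure")
    g <- addConcept(g, cc)
    g <- addRelation(g, cc, "IS_A", bodyRoot)
  }

  # anatomic containment (PART_OF)
  partOf <- list(
    c("Nucleolus", "Nucleus"), c("Nucleus", "Cell"), c("Cell", "Tissue"),
    c("Tissue", "Organ"), c("Margin", "Specimen"))
  for (pr in partOf)
    g <- addRelation(g, resolveConcept(g, pr[1]), "PART_OF",
                     resolveConcept(g, pr[2]))

  # property -> target links from the packaged equivalence rows and recipes
  eqRows <- .readTSV(aptermsFile("equivalence.tsv"))
  rec <- .readTSV(aptermsFile("recipes.tsv"))
  links <- unique(rbind(eqRows[, c("property", "target")],
                        rec[, c("property", "target")]))
  for (i in seq_len(nrow(links))) {
    pc <- resolveConcept(g, links$property[i])
    tc <- resolveConcept(g, links$target[i])
    g <- addRelation(g, pc, "HAS_TARGET", tc)
  }

  g@roles <- list(
    target = vapply(tabs$target, conceptKey, character(1)),
    property = vapply(tabs$property, conceptKey, character(1)),
    qualifier = c(vapply(tabs$qualifier, conceptKey, character(1)),
                  conceptKey(methodRoot)),
    method = conceptKey(methodRoot),
    locator = conceptKey(bodyRoot),
    problem = conceptKey(problemRoot)
  )
  validObject(g)
  g
}

#' Load the packaged equivalence table and recipe catalog
#'
#' The equivalence table carries the 17 packaged interface-to-generic rows
#' (element-name pattern, generic element, family, expression recipe, APSR
#' template OID with an example flag, and transcription notes). The recipe
#' catalog expands the generic inventory to the 53 distinct generic elements
#' of the default registry reconstruction, each with its name pattern,
#' family, expression recipe, enumerated value set (empty for quantitative
#' elements) and default context multiplicity.
#'
#' @return an [EquivalenceTable-class].
#' @export
loadEquivalenceTable <- function() {
  rows <- .readTSV(aptermsFile("equivalence.tsv"))
  recipes <- .readTSV(aptermsFile("recipes.tsv"))
  new("EquivalenceTable", rows = rows, recipes = recipes)
}

setMethod("show", "EquivalenceTable", function(object) {
  cat(sprintf("EquivalenceTable: %d equivalence rows, %d recipes (%s)\n",
              nrow(object@rows), nrow(object@recipes),
              paste(sprintf("%s: %d", names(table(object@recipes$family)),
                            as.integer(table(object@recipes$family))),
                    collapse = ", ")))
})
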