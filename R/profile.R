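#' Create a composition profile
#'
#' @param organs organ tokens.
#' @param problems problem tokens used in template names.
#' @param contextsPerFamily named vector: `(organ, problem)` contexts per
#'   recipe for each generic-element family.
#' @param specificElements,specificOccurrences element names and per-element
#'   context multiplicities for organ/disease-specific templates.
#' @param specificValueSet base value set of specific templates (perturbed
#'   in one context per element so the genericity criterion fails).
#' @param procedureNames procedure template names.
#' @param oidBranch reserved dotted-decimal branch for sequential OIDs.
#' @param seed random seed driving context sampling.
#' @return a [CompositionProfile-class].
#' @export
compositionProfile <- function(organs = defaultOrgans(),
                               problems = c("Invasive neoplasm",
                                            "In situ neoplasm"),
                               contextsPerFamily = c(
                                 core_generic = 20,
                                 staging_grading_classification = 8,
                                 marker = 3,
                                 unclassified_generic = 1),
                               specificElements = character(0),
                               specificOccurrences = numeric(0),
                               specificValueSet = c("absent", "present",
                                                    "marked"),
                               procedureNames = character(0),
                               oidBranch = "2.25.42424242.4",
                               seed = 0) {
  new("CompositionProfile", organs = organs, problems = problems,
      contextsPerFamily = contextsPerFamily,
      specificElements = specificElements,
      specificOccurrences = specificOccurrences,
      specificValueSet = specificValueSet,
      procedureNames = procedureNames, oidBranch = oidBranch, seed = seed)
}

#' The packaged default composition profile
#'
#' Reconstructs the published registry composition: 53 distinct generic
#' elements (9 core-generic recipes expanded over 20 contexts each, 28
#' staging/grading/classification over 8 each, 15 marker over 3 each, one
#' unclassified-generic slot over a single context), 17 organ/disease-
#' specific templates over 6 elements, and 21 procedure templates — 467
#' observation templates and 488 templates in total, spanning 20 organs.
#' The expansion multiplicities, the organ tokens, the specific-element
#' names and the procedure names are profile data and a reconstruction, not
#' transcribed source content.
#'
#' @param seed random seed for context sampling (the breakdown counts are
#'   seed-invariant).
#' @param path profile JSON to load; defaults to the packaged one.
#' @return a [CompositionProfile-class].
#' @examples
#' defaultProfile()
#' @export
defaultProfile <- function(seed = NULL, path = NULL) {
  if (is.null(path)) path <- aptermsFile("profile_default.json")
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  compositionProfile(
    organs = defaultOrgans(),
    problems = p$problems,
    contextsPerFamily = unlist(p$contexts_per_family),
    specificElements = p$specific_elements,
    specificOccurrences = p$specific_occurrences,
    specificValueSet = p$specific_value_set,
    procedureNames = p$procedure_names,
    oidBranch = p$oid_branch,
    seed = if (is.null(seed)) p$seed else seed)
}

#' Template counts implied by a profile
#'
#' @param profile a [CompositionProfile-class].
#' @param eq an [EquivalenceTable-class] (for per-family recipe counts).
#' @return named numeric vector: templates per family, observations, total.
#' @export
profileCounts <- function(profile, eq = loadEquivalenceTable()) {
  famN <- table(eq@recipes$family)
  perFam <- vapply(names(profile@contextsPerFamily), function(f)
    unname(profile@contextsPerFamily[[f]]) *
      (if (f %in% names(famN)) as.numeric(famN[[f]]) else 0),
    numeric(1))
  generic <- sum(perFam)
  specific <- sum(profile@specificOccurrences)
  procedures <- length(profile@procedureNames)
  c(perFam,
    specific = specific,
    procedures = procedures,
    observations = generic + specific,
    total = generic + specific + procedures)
}

setMethod("show", "CompositionProfile", function(object) {
  cat(sprintf(
    "CompositionProfile: %d organs x %d problems; contexts/recipe: %s; %d specific templates (%d elements); %d procedures; seed %d\n",
    length(object@organs), length(object@problems),
    paste(sprintf("%s=%g", names(object@contextsPerFamily),
                  object@contextsPerFamily), collapse = ", "),
    sum(object@specificOccurrences), length(object@specificElements),
    length(object@procedureNames), object@seed))
})
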