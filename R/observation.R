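#' Create an observation value
#'
#' Exactly one of `coded` or (`magnitude`, `unit`) must be given.
#'
#' @param coded a [ConceptRef-class] coded value.
#' @param magnitude finite decimal magnitude.
#' @param unit UCUM-style unit token (e.g. `"mm"`, `"g"`).
#' @return an [ObservationValue-class].
#' @examples
#' obsValue(magnitude = 12.5, unit = "mm")
#' @export
obsValue <- function(coded = NULL, magnitude = NULL, unit = NULL) {
  new("ObservationValue", coded = coded,
      magnitude = if (is.null(magnitude)) numeric(0) else as.numeric(magnitude),
      unit = if (is.null(unit)) character(0) else as.character(unit))
}

#' Create an observation context
#'
#' @param locator organ / body-site concept, or `NULL`.
#' @param problem pathological-problem organizer concept, or `NULL`.
#' @param method observation-method qualifier concept, or `NULL`.
#' @return a [Context-class].
#' @export
obsContext <- function(locator = NULL, problem = NULL, method = NULL) {
  new("Context", locator = locator, problem = problem, method = method)
}

.roleCheck <- function(graph, concept, role, errs) {
  roots <- graph@roles[[role]]
  if (is.null(roots) || !length(roots)) return(errs)
  anc <- tryCatch(conceptClosure(graph, concept, "IS_A"),
                  apMissingConceptError = function(e) NULL)
  if (is.null(anc))
    return(c(errs, sprintf("%s: concept %s is not registered in the graph",
                           role, conceptKey(concept))))
  if (!any(roots %in% anc))
    c(errs, sprintf("%s: concept '%s' (%s) is not permissible under any %s root",
                    role, concept@designation, conceptKey(concept), role))
  else errs
}

#' Compose and validate a generic observation expression
#'
#' Builds a [GenericObservation-class] from its components and validates
#' every role against the graph's permissible-value roots (a concept fills a
#' role when some root is among its `IS_A` ancestors). Validation errors are
#' aggregated: one constraint error names every offending role and concept,
#' not only the first. Qualifiers are canonicalized by sorting on
#' `(namespace, code)`; duplicates are normalized silently.
#'
#' @param graph an [OntologyGraph-class] whose `roles` define the
#'   permissible-value roots.
#' @param target,property concept for the target/property role
#'   ([ConceptRef-class], key or designation).
#' @param qualifiers list (or vector) of qualifier concepts.
#' @param context a [Context-class], or `NULL` for a context-free expression.
#' @param value an [ObservationValue-class] or `NULL`.
#' @return a canonicalized, validated [GenericObservation-class].
#' @examples
#' g <- buildReferenceOntology()
#' composeObservation(g, target = "Specimen", property = "Weight")
#' @export
composeObservation <- function(graph, target, property, qualifiers = list(),
                               context = obsContext(), value = NULL) {
  if (is.null(context)) context <- obsContext()
  if (!is.list(qualifiers)) qualifiers <- as.list(qualifiers)

  errs <- character()
  res <- function(x, role) {
    tryCatch(resolveConcept(graph, x), aptermsError = function(e) {
      errs <<- c(errs, sprintf("%s: %s", role, conditionMessage(e)))
      NULL
    })
  }
  tc <- res(target, "target")
  pc <- res(property, "property")
  qs <- lapply(qualifiers, res, role = "qualifier")
  loc <- if (!is.null(context@locator)) res(context@locator, "locator")
  prob <- if (!is.null(context@problem)) res(context@problem, "problem")
  meth <- if (!is.null(context@method)) res(context@method, "method")

  if (!is.null(tc)) errs <- .roleCheck(graph, tc, "target", errs)
  if (!is.null(pc)) errs <- .roleCheck(graph, pc, "property", errs)
  for (q in qs) if (!is.null(q)) errs <- .roleCheck(graph, q, "qualifier", errs)
  if (!is.null(loc)) errs <- .roleCheck(graph, loc, "locator", errs)
  if (!is.null(prob)) errs <- .roleCheck(graph, prob, "problem", errs)
  if (!is.null(meth)) errs <- .roleCheck(graph, meth, "method", errs)
  if (!is.null(value)) {
    v <- tryCatch({ validObject(value); NULL }, error = function(e)
      sprintf("value: %s", conditionMessage(e)))
    errs <- c(errs, v)
    if (!is.null(value@coded)) {
      cv <- tryCatch(resolveConcept(graph, value@coded),
                     aptermsError = function(e) {
                       errs <<- c(errs, sprintf("value: %s", conditionMessage(e)))
                       NULL
                     })
    }
  }
  if (length(errs)) apConstraint(errs)

  # canonical qualifier order: sort by (namespace, code), deduplicate
  qs <- qs[!vapply(qs, is.null, logical(1))]
  keys <- vapply(qs, conceptKey, character(1))
  qs <- qs[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  qs <- qs[order(keys, method = "radix")]

  new("GenericObservation",
      context = obsContext(locator = loc, problem = prob, method = meth),
      target = tc, property = pc, qualifiers = qs, value = value,
      graphId = graphSignature(graph))
}

.slotKey <- function(x) if (is.null(x)) "" else conceptKey(x)

#' Canonical identity string of an expression
#'
#' Two expressions are canonically equal iff their keys are equal: same
#' target, property, qualifier set, context slots and value.
#'
#' @param expr a [GenericObservation-class].
#' @return character(1).
#' @export
observationKey <- function(expr) {
  v <- expr@value
  vs <- if (is.null(v)) "" else if (!is.null(v@coded)) {
    paste0("coded:", conceptKey(v@coded))
  } else sprintf("qty:%.12g:%s", v@magnitude, v@unit)
  paste(
    paste0("t=", .slotKey(expr@target)),
    paste0("p=", .slotKey(expr@property)),
    paste0("q=", paste(vapply(expr@qualifiers, conceptKey, character(1)),
                       collapse = ",")),
    paste0("loc=", .slotKey(expr@context@locator)),
    paste0("prob=", .slotKey(expr@context@problem)),
    paste0("m=", .slotKey(expr@context@method)),
    paste0("val=", vs),
    sep = ";")
}

.isaMatch <- function(graph, generalKey, specificKey) {
  generalKey %in% .reach(graph@edges, "IS_A", specificKey)
}

#' Subsumption between generic observation expressions
#'
#' `subsumes(a, b, graph)` is `TRUE` when `a` is at least as general as `b`:
#' each of `a`'s filled slots (target, property, locator, problem, method)
#' is an `IS_A` ancestor-or-self of `b`'s corresponding slot (an absent slot
#' in `a` matches anything, an absent slot in `b` fails a filled slot in
#' `a`), and every qualifier of `a` subsumes some qualifier of `b` (`a`'s
#' qualifier set is a subset of `b`'s under `IS_A` matching). The relation
#' is a preorder: reflexive and transitive. Values are not compared.
#'
#' Both expressions must have been composed against the supplied graph;
#' otherwise a graph-mismatch error is raised.
#'
#' @param a,b [GenericObservation-class] expressions.
#' @param graph the [OntologyGraph-class] both were validated against.
#' @return logical(1).
#' @rdname subsumes
#' @export
setMethod("subsumes", signature("GenericObservation", "GenericObservation"),
  function(a, b, graph) {
    sig <- graphSignature(graph)
    if (!identical(a@graphId, sig) || !identical(b@graphId, sig))
      apGraphMismatch("expressions were not composed against the supplied graph")

    slotPair <- function(sa, sb) {
      if (is.null(sa)) return(TRUE)
      if (is.null(sb)) return(FALSE)
      .isaMatch(graph, conceptKey(sa), conceptKey(sb))
    }
    if (!slotPair(a@target, b@target)) return(FALSE)
    if (!slotPair(a@property, b@property)) return(FALSE)
    if (!slotPair(a@context@locator, b@context@locator)) return(FALSE)
    if (!slotPair(a@context@problem, b@context@problem)) return(FALSE)
    if (!slotPair(a@context@method, b@context@method)) return(FALSE)
    for (qa in a@qualifiers) {
      ok <- any(vapply(b@qualifiers, function(qb)
        .isaMatch(graph, conceptKey(qa), conceptKey(qb)), logical(1)))
      if (!ok) return(FALSE)
    }
    TRUE
  })

#' One-line canonical rendering of an expression
#'
#' @param expr a [GenericObservation-class].
#' @return character(1) human-readable dump, e.g.
#'   `"Diameter (property) OF Lesion (target) QUALIFIED-BY
#'   ObservedByMicroscopicInvestigation, Largest LOCATOR Breast PROBLEM
#'   non-invasive tumor"`.
#' @export
formatObservation <- function(expr) {
  quals <- c(
    if (!is.null(expr@context@method)) expr@context@method@designation,
    vapply(expr@qualifiers, function(q) q@designation, character(1)))
  parts <- c(
    sprintf("%s (property) OF %s (target)",
            expr@property@designation, expr@target@designation),
    if (length(quals)) paste("QUALIFIED-BY", paste(quals, collapse = ", ")),
    if (!is.null(expr@context@locator))
      paste("LOCATOR", expr@context@locator@designation),
    if (!is.null(expr@context@problem))
      paste("PROBLEM", expr@context@problem@designation),
    if (!is.null(expr@value)) {
      v <- expr@value
      if (!is.null(v@coded)) paste("VALUE", v@coded@designation)
      else sprintf("VALUE %g %s", v@magnitude, v@unit)
    })
  paste(parts, collapse = " ")
}

setMethod("show", "GenericObservation", function(object) {
  cat("<GenericObservation>", formatObservation(object), "\n")
})

setMethod("show", "Context", function(object) {
  d <- function(x) if (is.null(x)) "-" else x@designation
  cat(sprintf("<Context> locator: %s | problem: %s | method: %s\n",
              d(object@locator), d(object@problem), d(object@method)))
})
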