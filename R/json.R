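.conceptToList <- function(c1) {
  if (is.null(c1)) return(NULL)
  list(code = c1@code, namespace = c1@namespace, designation = c1@designation)
}

#' Serialize an expression to JSON
#'
#' Deterministic canonical JSON: fixed key order, qualifiers in canonical
#' order, absent slots as `null`. Concepts are written as
#' `{code, namespace, designation}`; [expressionFromJSON()] re-resolves them
#' against a graph, so the round trip preserves canonical equality.
#'
#' @param expr a [GenericObservation-class].
#' @param pretty pretty-print the JSON.
#' @return character(1) JSON.
#' @export
expressionToJSON <- function(expr, pretty = FALSE) {
  v <- expr@value
  valueList <- if (is.null(v)) NULL else if (!is.null(v@coded)) {
    list(coded = .conceptToList(v@coded))
  } else list(quantity = list(magnitude = v@magnitude, unit = v@unit))
  x <- list(
    context = list(
      locator = .conceptToList(expr@context@locator),
      problem = .conceptToList(expr@context@problem),
      method = .conceptToList(expr@context@method)
    ),
    target = .conceptToList(expr@target),
    property = .conceptToList(expr@property),
    qualifiers = lapply(expr@qualifiers, .conceptToList),
    value = valueList
  )
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                                digits = NA, pretty = pretty))
}

.conceptFromList <- function(x, graph) {
  if (is.null(x)) return(NULL)
  conceptAt(graph, paste(x$namespace, x$code, sep = ":"))
}

#' Parse an expression from JSON
#'
#' @param txt JSON produced by [expressionToJSON()] (or a parsed list).
#' @param graph the [OntologyGraph-class] to resolve concepts against.
#' @return a [GenericObservation-class], re-composed and validated.
#' @export
expressionFromJSON <- function(txt, graph) {
  x <- if (is.character(txt))
    jsonlite::fromJSON(txt, simplifyVector = FALSE) else txt
  value <- if (!is.null(x$value)) {
    if (!is.null(x$value$coded))
      obsValue(coded = .conceptFromList(x$value$coded, graph))
    else obsValue(magnitude = x$value$quantity$magnitude,
                  unit = x$value$quantity$unit)
  }
  composeObservation(
    graph,
    target = .conceptFromList(x$target, graph),
    property = .conceptFromList(x$property, graph),
    qualifiers = lapply(x$qualifiers, .conceptFromList, graph = graph),
    context = obsContext(
      locator = .conceptFromList(x$context$locator, graph),
      problem = .conceptFromList(x$context$problem, graph),
      method = .conceptFromList(x$context$method, graph)),
    value = value)
}
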