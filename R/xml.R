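## HL7-template-style XML dialect (artifact-defined; CDA-compatible
## conventions without claiming CDA conformance):
##  - lower-camel element names
##  - SNOMED codes in code/@code with codeSystem fixed to the SNOMED CT OID
##  - local concepts under a repo-reserved OID branch
##  - the property element carries relationship="HAS-TARGET", qualifier and
##    method elements carry relationship="IS-QUALIFIER-OF"

#' @rdname writeExpressionXML
#' @export
snomedCodeSystemOID <- function() "2.16.840.1.113883.6.96"

#' @rdname writeExpressionXML
#' @export
localCodeSystemOID <- function() "2.25.42424242.1"

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

.xmlCode <- function(c1) {
  cs <- if (identical(c1@namespace, "snomed")) snomedCodeSystemOID()
        else localCodeSystemOID()
  sprintf('<code code="%s" codeSystem="%s" displayName="%s"%s/>',
          .xmlEscape(c1@code), cs, .xmlEscape(c1@designation),
          if (isTRUE(c1@approximate)) ' approximate="true"' else "")
}

.xmlCoded <- function(name, c1, indent, relationship = NULL) {
  rel <- if (is.null(relationship)) "" else
    sprintf(' relationship="%s"', relationship)
  pad <- strrep(" ", indent)
  paste0(pad, "<", name, rel, ">\n",
         pad, "  ", .xmlCode(c1), "\n",
         pad, "</", name, ">")
}

#' Write an expression as HL7-template-style XML
#'
#' Produces a deterministic, byte-stable document: fixed element and
#' attribute order, fixed namespace declaration, two-space indentation. The
#' property element carries `relationship="HAS-TARGET"` (it points at the
#' sibling target element); qualifier and method elements carry
#' `relationship="IS-QUALIFIER-OF"`. Locator and problem organizer are
#' sibling context elements. Every emitted document validates against the
#' shipped XSD ([observationSchema()]).
#'
#' @param expr a [GenericObservation-class].
#' @param path optional file to write to.
#' @return character(1) XML document (invisibly when `path` is given).
#' @export
writeExpressionXML <- function(expr, path = NULL) {
  ctx <- character(0)
  if (!is.null(expr@context@locator))
    ctx <- c(ctx, .xmlCoded("locator", expr@context@locator, 4))
  if (!is.null(expr@context@problem))
    ctx <- c(ctx, .xmlCoded("problemOrganizer", expr@context@problem, 4))
  if (!is.null(expr@context@method))
    ctx <- c(ctx, .xmlCoded("method", expr@context@method, 4,
                            relationship = "IS-QUALIFIER-OF"))
  ctxBlock <- if (length(ctx))
    paste0("  <context>\n", paste(ctx, collapse = "\n"), "\n  </context>")
  else "  <context/>"

  body <- c(
    ctxBlock,
    .xmlCoded("target", expr@target, 2),
    .xmlCoded("property", expr@property, 2, relationship = "HAS-TARGET"),
    vapply(expr@qualifiers, function(q)
      .xmlCoded("qualifier", q, 2, relationship = "IS-QUALIFIER-OF"),
      character(1))
  )
  if (!is.null(expr@value)) {
    v <- expr@value
    inner <- if (!is.null(v@coded)) .xmlCode(v@coded) else
      sprintf('<quantity value="%.12g" unit="%s"/>', v@magnitude,
              .xmlEscape(v@unit))
    body <- c(body, paste0("  <value>\n    ", inner, "\n  </value>"))
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<observation xmlns="urn:apterms:observation:1">\n',
    paste(body, collapse = "\n"), "\n",
    "</observation>\n")
  if (!is.null(path)) {
    writeLines(doc, path, sep = "")
    return(invisible(doc))
  }
  doc
}

#' Path to the shipped observation XSD
#' @return character(1) file path.
#' @export
observationSchema <- function() aptermsFile(file.path("schema", "observation.xsd"))

#' Validate an observation XML document against the shipped schema
#'
#' @param doc XML string, file path or `xml2` document.
#' @return logical(1); attribute `"errors"` carries validation messages.
#' @export
validateExpressionXML <- function(doc) {
  x <- if (inherits(doc, "xml_document")) doc else xml2::read_xml(doc)
  xml2::xml_validate(x, xml2::read_xml(observationSchema()))
}

.xmlConcept <- function(node, graph) {
  code <- xml2::xml_find_first(node, "./code")
  cs <- xml2::xml_attr(code, "codeSystem")
  ns <- if (identical(cs, snomedCodeSystemOID())) "snomed" else "local"
  conceptAt(graph, paste(ns, xml2::xml_attr(code, "code"), sep = ":"))
}

#' Read an expression from HL7-template-style XML
#'
#' Inverse of [writeExpressionXML()]: concepts are resolved against the
#' graph and the expression is re-composed (validated, canonicalized), so
#' `readExpressionXML(writeExpressionXML(e), g)` is canonically equal to `e`.
#'
#' @param doc XML string, file path or `xml2` document.
#' @param graph the [OntologyGraph-class] to resolve concepts against.
#' @return a [GenericObservation-class].
#' @export
readExpressionXML <- function(doc, graph) {
  x <- if (inherits(doc, "xml_document")) doc else xml2::read_xml(doc)
  x <- xml2::xml_ns_strip(x)
  f1 <- function(xp) {
    n <- xml2::xml_find_first(x, xp)
    if (inherits(n, "xml_missing")) NULL else n
  }
  getc <- function(xp) {
    n <- f1(xp)
    if (is.null(n)) NULL else .xmlConcept(n, graph)
  }
  quals <- lapply(xml2::xml_find_all(x, "./qualifier"), .xmlConcept, graph = graph)
  value <- NULL
  vn <- f1("./value")
  if (!is.null(vn)) {
    qn <- xml2::xml_find_first(vn, "./quantity")
    if (!inherits(qn, "xml_missing")) {
      value <- obsValue(magnitude = as.numeric(xml2::xml_attr(qn, "value")),
                        unit = xml2::xml_attr(qn, "unit"))
    } else {
      cn <- xml2::xml_find_first(vn, "./code")
      cs <- xml2::xml_attr(cn, "codeSystem")
      ns <- if (identical(cs, snomedCodeSystemOID())) "snomed" else "local"
      value <- obsValue(coded = conceptAt(
        graph, paste(ns, xml2::xml_attr(cn, "code"), sep = ":")))
    }
  }
  composeObservation(
    graph,
    target = getc("./target"),
    property = getc("./property"),
    qualifiers = quals,
    context = obsContext(
      locator = getc("./context/locator"),
      problem = getc("./context/problemOrganizer"),
      method = getc("./context/method")),
    value = value)
}
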