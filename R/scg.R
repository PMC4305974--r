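## Compositional-grammar-style dialect
##
## expr       := focus [ ":" refinement { "," refinement } ]
## focus      := concept                       (the target)
## refinement := concept                       (bare concept = the property)
##             | "qual"   "=" concept
##             | "loc"    "=" concept
##             | "prob"   "=" concept
##             | "method" "=" concept
##             | "val"    "=" concept | "#" number unit
## concept    := code "|" designation "|"      (local codes prefixed "ap:")

.scgConcept <- function(c1) {
  code <- if (identical(c1@namespace, "local")) paste0("ap:", c1@code) else c1@code
  sprintf("%s |%s|", code, c1@designation)
}

#' Render an expression as a compositional-grammar string
#'
#' Deterministic rendering: the target is the focus concept; the property is
#' the first (bare) refinement; qualifiers, locator, problem organizer,
#' method and value follow as named attribute-value pairs in fixed order.
#' Local concepts carry the reserved `ap:` code prefix. The output is stable
#' across runs for a canonical expression and re-parses to an equal
#' expression with [parseSCG()].
#'
#' @param expr a [GenericObservation-class].
#' @return character(1), e.g. `"123038009 |Specimen| : 272102008 |Weight|"`.
#' @rdname toSCG
#' @export
setMethod("toSCG", "GenericObservation", function(expr) {
  ref <- character(0)
  ref <- c(ref, .scgConcept(expr@property))
  for (q in expr@qualifiers) ref <- c(ref, paste("qual =", .scgConcept(q)))
  if (!is.null(expr@context@locator))
    ref <- c(ref, paste("loc =", .scgConcept(expr@context@locator)))
  if (!is.null(expr@context@problem))
    ref <- c(ref, paste("prob =", .scgConcept(expr@context@problem)))
  if (!is.null(expr@context@method))
    ref <- c(ref, paste("method =", .scgConcept(expr@context@method)))
  if (!is.null(expr@value)) {
    v <- expr@value
    ref <- c(ref, if (!is.null(v@coded)) paste("val =", .scgConcept(v@coded))
             else sprintf("val = #%.12g %s", v@magnitude, v@unit))
  }
  if (!length(ref)) return(.scgConcept(expr@target))
  paste(.scgConcept(expr@target), ":", paste(ref, collapse = ", "))
})

## split on top-level commas (commas inside |...| designations are literal)
.scgSplit <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  out <- character(0)
  buf <- character(0)
  inPipe <- FALSE
  for (ch in chars) {
    if (ch == "|") inPipe <- !inPipe
    if (ch == "," && !inPipe) {
      out <- c(out, paste(buf, collapse = ""))
      buf <- character(0)
    } else buf <- c(buf, ch)
  }
  c(out, paste(buf, collapse = ""))
}

.scgParseConcept <- function(txt, graph) {
  m <- regmatches(txt, regexec("^\\s*([A-Za-z0-9:._-]+)\\s*\\|([^|]*)\\|\\s*$", txt))[[1]]
  if (length(m) != 3L) apParse(sprintf("cannot parse concept reference: '%s'", txt))
  code <- m[2]
  key <- if (startsWith(code, "ap:"))
    paste0("local:", substring(code, 4)) else paste0("snomed:", code)
  conceptAt(graph, key)
}

#' Parse a compositional-grammar string
#'
#' Inverse of [toSCG()]. Concept codes are resolved against `graph`, and the
#' result is re-composed (and therefore re-validated and canonicalized) with
#' [composeObservation()].
#'
#' @param txt a string produced by [toSCG()] (or in the same dialect).
#' @param graph the [OntologyGraph-class] to resolve concepts against.
#' @return a [GenericObservation-class].
#' @export
parseSCG <- function(txt, graph) {
  if (!nzchar(trimws(txt))) apParse("empty compositional-grammar string")
  # the focus runs up to the end of the first |...| block; splitting on ":"
  # would break local "ap:" code prefixes
  focusEnd <- regexpr("\\|[^|]*\\|", txt)
  if (focusEnd < 0) apParse(sprintf("no concept reference in '%s'", txt))
  cut <- focusEnd + attr(focusEnd, "match.length")
  focusTxt <- substr(txt, 1, cut - 1)
  rest <- trimws(substr(txt, cut, nchar(txt)))
  target <- .scgParseConcept(focusTxt, graph)
  property <- NULL; qualifiers <- list()
  locator <- NULL; problem <- NULL; method <- NULL; value <- NULL
  if (nzchar(rest)) {
    if (!startsWith(rest, ":"))
      apParse(sprintf("expected ':' before refinements in '%s'", txt))
    for (tok in .scgSplit(substring(rest, 2))) {
      tok <- trimws(tok)
      if (grepl("^(qual|loc|prob|method|val)\\s*=", tok)) {
        attrName <- sub("\\s*=.*$", "", tok)
        rhs <- trimws(sub("^[a-z]+\\s*=\\s*", "", tok))
        if (attrName == "val" && startsWith(rhs, "#")) {
          qm <- regmatches(rhs, regexec("^#([-0-9.eE+]+)\\s+(\\S+)$", rhs))[[1]]
          if (length(qm) != 3L) apParse(sprintf("cannot parse quantity '%s'", rhs))
          value <- obsValue(magnitude = as.numeric(qm[2]), unit = qm[3])
        } else {
          cc <- .scgParseConcept(rhs, graph)
          switch(attrName,
                 qual = { qualifiers <- c(qualifiers, cc) },
                 loc = { locator <- cc },
                 prob = { problem <- cc },
                 method = { method <- cc },
                 val = { value <- obsValue(coded = cc) })
        }
      } else {
        if (!is.null(property))
          apParse("more than one bare (property) refinement")
        property <- .scgParseConcept(tok, graph)
      }
    }
  }
  if (is.null(property))
    apParse("expression has no property refinement")
  composeObservation(graph, target = target, property = property,
                     qualifiers = qualifiers,
                     context = obsContext(locator, problem, method),
                     value = value)
}
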