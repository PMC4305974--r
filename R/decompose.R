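#' Name grammar for precoordinated template names
#'
#' Template names follow `Organ-Problem-Element` with a single-character
#' context delimiter and at most two context segments. The organ lexicon
#' disambiguates hyphens inside element names: a name is only split when its
#' first segment is a known organ token (commas and spaces are never
#' delimiters), so names like `"Ki-67"` or `"BI-RADS category"` stay whole.
#'
#' @param delimiter context delimiter, `"-"` by default.
#' @param organs organ lexicon used to recognize context-bearing names.
#' @return a list of class `"nameGrammar"`.
#' @export
nameGrammar <- function(delimiter = "-", organs = defaultOrgans()) {
  structure(list(delimiter = delimiter, organs = organs),
            class = "nameGrammar")
}

#' Parse a template name into context and element
#'
#' @param name template display name.
#' @param grammar a [nameGrammar()].
#' @return list with fields `organ`, `problem` (both `NA` when absent) and
#'   `element` (never empty).
#' @examples
#' parseName("Breast-In situ neoplasm-Lesion size, largest dimension")
#' parseName("Specimen weight")
#' @export
parseName <- function(name, grammar = nameGrammar()) {
  if (length(name) != 1L || is.na(name) || !nzchar(name))
    apParse("cannot parse an empty template name")
  parts <- strsplit(name, grammar$delimiter, fixed = TRUE)[[1]]
  if (!length(parts) || !any(nzchar(parts)))
    apParse(sprintf("template name is all delimiters: '%s'", name))
  lowOrgans <- tolower(grammar$organs)
  if (length(parts) >= 2L && tolower(parts[1]) %in% lowOrgans) {
    organ <- grammar$organs[match(tolower(parts[1]), lowOrgans)]
    if (length(parts) >= 3L) {
      element <- paste(parts[-(1:2)], collapse = grammar$delimiter)
      if (!nzchar(element)) apParse(sprintf("empty element in '%s'", name))
      return(list(organ = organ, problem = parts[2], element = element))
    }
    return(list(organ = organ, problem = NA_character_, element = parts[2]))
  }
  list(organ = NA_character_, problem = NA_character_, element = name)
}

## bounded case-insensitive pattern match: the pattern must appear as a
## whole token run (non-alphanumeric or string boundary on both sides)
.patternHits <- function(element, patterns) {
  hits <- vapply(patterns, function(p) {
    rx <- paste0("(^|[^[:alnum:]])", .rxQuote(p), "([^[:alnum:]]|$)")
    grepl(rx, element, ignore.case = TRUE)
  }, logical(1))
  which(hits)
}

.rxQuote <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

## match an element name against the recipe catalog, then the equivalence
## rows; longest pattern wins, ties break lexicographically on designation
## (with a warning)
.matchElement <- function(element, eq) {
  for (layer in list(
    data.frame(pattern = eq@recipes$pattern,
               designation = eq@recipes$designation,
               family = eq@recipes$family,
               target = eq@recipes$target, property = eq@recipes$property,
               qualifiers = eq@recipes$qualifiers, method = eq@recipes$method,
               stringsAsFactors = FALSE),
    data.frame(pattern = eq@rows$pattern, designation = eq@rows$element,
               family = eq@rows$family,
               target = eq@rows$target, property = eq@rows$property,
               qualifiers = eq@rows$qualifiers, method = eq@rows$method,
               stringsAsFactors = FALSE))) {
    idx <- .patternHits(element, layer$pattern)
    if (!length(idx)) next
    lens <- nchar(layer$pattern[idx])
    idx <- idx[lens == max(lens)]
    if (length(idx) > 1L) {
      ord <- order(layer$designation[idx], method = "radix")
      warning(sprintf(
        "element '%s' matches several equal-length patterns (%s); using '%s'",
        element, paste(layer$designation[idx], collapse = ", "),
        layer$designation[idx[ord[1]]]), call. = FALSE)
      idx <- idx[ord[1]]
    }
    return(layer[idx, , drop = FALSE])
  }
  NULL
}

.termFields <- function(term) {
  if (is(term, "PrecoordinatedTerm"))
    return(list(oid = term@oid, name = term@name, category = term@category,
                value_set = term@value_set))
  if (is.data.frame(term)) {
    stopifnot(nrow(term) == 1L)
    return(list(oid = term$oid, name = term$name, category = term$category,
                value_set = term$value_set[[1]]))
  }
  list(oid = term$oid, name = term$name,
       category = term$category %||% "observation",
       value_set = term$value_set %||% character(0))
}

#' Decompose a precoordinated term into a generic expression
#'
#' Procedure-category terms get the verdict `"procedure"`. For observations
#' the element part of the name (after [parseName()]) is matched against the
#' recipe catalog and the equivalence rows, longest pattern first,
#' case-insensitively. On a match the canonical [GenericObservation-class]
#' is built from the matched recipe (target, property, qualifiers, method)
#' with the locator and problem organizer resolved from the parsed name
#' context. Unmatched observations get the verdict `"specific"` with a
#' reason; that is a result, not an error.
#'
#' @param term a [PrecoordinatedTerm-class], a one-row registry data.frame,
#'   or a list with fields oid, name, category, value_set.
#' @param eq an [EquivalenceTable-class].
#' @param graph the reference [OntologyGraph-class].
#' @param grammar a [nameGrammar()].
#' @return a [DecompositionResult-class].
#' @examples
#' g <- buildReferenceOntology(); eq <- loadEquivalenceTable()
#' t1 <- precoordinatedTerm("1.3.6.1.4.1.19376.1.8.1.4.160", "Specimen weight")
#' decomposeTerm(t1, eq, g)
#' @rdname decomposeTerm
#' @export
setMethod("decomposeTerm", "ANY", function(term, eq, graph,
                                           grammar = nameGrammar()) {
  tf <- .termFields(term)
  if (identical(tf$category, "procedure"))
    return(new("DecompositionResult", verdict = "procedure"))
  parsed <- parseName(tf$name, grammar)
  hit <- .matchElement(parsed$element, eq)
  if (is.null(hit))
    return(new("DecompositionResult", verdict = "specific",
               unmatchedReason = sprintf(
                 "element '%s' matches no equivalence pattern", parsed$element)))

  resolveOrCfg <- function(x, what) {
    tryCatch(resolveConcept(graph, x), aptermsError = function(e)
      apConfig(sprintf("equivalence recipe for '%s' references unknown %s '%s'",
                       hit$designation, what, x)))
  }
  target <- resolveOrCfg(hit$target, "target concept")
  property <- resolveOrCfg(hit$property, "property concept")
  quals <- list()
  if (nzchar(hit$qualifiers %||% ""))
    quals <- lapply(strsplit(hit$qualifiers, "|", fixed = TRUE)[[1]],
                    resolveOrCfg, what = "qualifier concept")
  method <- if (nzchar(hit$method %||% "")) resolveOrCfg(hit$method, "method concept")

  locator <- if (!is.na(parsed$organ))
    tryCatch(resolveConcept(graph, parsed$organ), aptermsError = function(e) NULL)
  problem <- NULL
  if (!is.na(parsed$problem)) {
    lex <- problemLexicon()
    j <- match(tolower(parsed$problem), tolower(lex$token))
    probDesignation <- if (!is.na(j)) lex$problem[j] else parsed$problem
    problem <- tryCatch(resolveConcept(graph, probDesignation),
                        aptermsError = function(e) NULL)
  }
  expr <- composeObservation(
    graph, target = target, property = property, qualifiers = quals,
    context = obsContext(locator = locator, problem = problem, method = method))
  new("DecompositionResult", verdict = "generic", expression = expr,
      matchedGenericElement = hit$designation, family = hit$family)
})

setMethod("show", "DecompositionResult", function(object) {
  cat(sprintf("<DecompositionResult> verdict: %s", object@verdict))
  if (!is.na(object@matchedGenericElement))
    cat(sprintf(" | element: %s (%s)", object@matchedGenericElement,
                object@family))
  if (!is.na(object@unmatchedReason))
    cat(sprintf(" | %s", object@unmatchedReason))
  cat("\n")
  if (!is.null(object@expression)) show(object@expression)
})

#' Decompose every registry row
#'
#' @param registry registry data.frame ([readRegistry()] /
#'   [generateRegistry()]).
#' @param eq an [EquivalenceTable-class].
#' @param graph the reference [OntologyGraph-class].
#' @param grammar a [nameGrammar()].
#' @return data.frame with one row per term: oid, name, verdict, element,
#'   family, organ, problem, reason.
#' @export
decomposeRegistry <- function(registry, eq, graph, grammar = nameGrammar()) {
  n <- nrow(registry)
  out <- data.frame(
    oid = registry$oid, name = registry$name,
    verdict = character(n), element = rep(NA_character_, n),
    family = rep(NA_character_, n), organ = rep(NA_character_, n),
    problem = rep(NA_character_, n), reason = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    res <- decomposeTerm(registry[i, , drop = FALSE], eq, graph, grammar)
    out$verdict[i] <- res@verdict
    out$element[i] <- res@matchedGenericElement
    out$family[i] <- res@family
    out$reason[i] <- res@unmatchedReason
    if (!identical(res@verdict, "procedure")) {
      p <- parseName(registry$name[i], grammar)
      out$organ[i] <- p$organ
      out$problem[i] <- p$problem
    }
  }
  out
}

#' Classify an element as generic or specific by value-set uniqueness
#'
#' An element is generic when it has a unique value set in each possible
#' application: every occurrence across all `(organ, problem)` contexts
#' carries the same value set (compared as sets, order-insensitively).
#' Otherwise it is specific and needs its own per-context value set. A
#' single occurrence is vacuously generic; set `strictSingle = TRUE` to
#' invert that policy and classify single-occurrence elements as specific.
#'
#' @param element element token (the element part of a template name).
#' @param registry registry data.frame.
#' @param grammar a [nameGrammar()].
#' @param strictSingle policy flag for single-occurrence elements.
#' @return `"generic"` or `"specific"`.
#' @export
classifyGenericity <- function(element, registry, grammar = nameGrammar(),
                               strictSingle = FALSE) {
  elements <- vapply(registry$name, function(nm)
    parseName(nm, grammar)$element, character(1), USE.NAMES = FALSE)
  idx <- which(tolower(elements) == tolower(element) &
                 registry$category == "observation")
  if (!length(idx))
    apNotFound(sprintf("element '%s' does not occur in the registry", element))
  if (length(idx) == 1L && strictSingle) return("specific")
  canon <- lapply(registry$value_set[idx], function(v)
    sort(unique(as.character(v)), method = "radix"))
  allEqual <- all(vapply(canon, identical, logical(1), y = canon[[1]]))
  if (allEqual) "generic" else "specific"
}

#' SNOMED mapping coverage of a concept collection
#'
#' Percentage of concepts carrying a nonempty SNOMED code, approximate
#' mappings included, reported to one decimal place. Duplicate concepts
#' (same namespace, code and designation) are de-duplicated first, so the
#' figure is invariant to repeated rows.
#'
#' @param concepts list of [ConceptRef-class] (e.g. from
#'   [loadValueSetTable()]) or a data.frame with `namespace`, `code`,
#'   `designation` columns.
#' @return numeric(1) percentage in `[0, 100]`.
#' @examples
#' snomedCoverage(c(loadValueSetTable("targets.tsv"),
#'                  loadValueSetTable("properties.tsv"),
#'                  loadValueSetTable("qualifiers.tsv")))
#' @export
snomedCoverage <- function(concepts) {
  if (is.data.frame(concepts)) {
    df <- concepts[, c("namespace", "code", "designation")]
  } else {
    if (!length(concepts)) apCoverageUndefined()
    df <- data.frame(
      namespace = vapply(concepts, function(c1) c1@namespace, character(1)),
      code = vapply(concepts, function(c1) c1@code, character(1)),
      designation = vapply(concepts, function(c1) c1@designation, character(1)),
      stringsAsFactors = FALSE)
  }
  df <- unique(df)
  if (!nrow(df)) apCoverageUndefined()
  round(100 * sum(df$namespace == "snomed") / nrow(df), 1)
}
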