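#' Create a concept reference
#'
#' @param code concept identifier: digits for SNOMED concepts; for local
#'   concepts the code defaults to a slug of the designation.
#' @param designation human-readable label.
#' @param namespace `"snomed"` or `"local"`.
#' @param axis optional SNOMED CT axis annotation (e.g. `"qualifier value"`).
#' @param approximate `TRUE` for tentative mappings (codes the source prints
#'   in parentheses).
#'
#' @return a [ConceptRef-class].
#' @examples
#' conceptRef("49755003", "Lesion", axis = "morphologic abnormality")
#' conceptRef(designation = "Breast", namespace = "local")
#' @export
conceptRef <- function(code = NULL, designation, namespace = "snomed",
                       axis = NA_character_, approximate = FALSE) {
  if (is.null(code) || !nzchar(code %||% "")) {
    namespace <- "local"
    code <- slugify(designation)
  }
  new("ConceptRef", code = as.character(code), namespace = namespace,
      designation = designation, axis = axis, approximate = approximate)
}

`%||%` <- function(x, y) if (is.null(x) || (length(x) == 1L && is.na(x))) y else x

#' @keywords internal
slugify <- function(x) {
  s <- tolower(x)
  s <- gsub("[^a-z0-9]+", "-", s)
  gsub("^-+|-+$", "", s)
}

#' Concept key
#'
#' Concept identity within a graph is the pair `(namespace, code)`, written
#' `"namespace:code"`.
#'
#' @param x a [ConceptRef-class] or a key string.
#' @return character(1) key.
#' @export
conceptKey <- function(x) {
  if (is(x, "ConceptRef")) paste(x@namespace, x@code, sep = ":") else as.character(x)
}

emptyConcepts <- function() {
  data.frame(key = character(), code = character(), namespace = character(),
             designation = character(), axis = character(),
             approximate = logical(), stringsAsFactors = FALSE)
}

emptyEdges <- function() {
  data.frame(child = character(), type = character(), parent = character(),
             stringsAsFactors = FALSE)
}

#' Create an empty ontology graph
#'
#' @param roles optional named list of permissible-value root keys per
#'   expression role (`target`, `property`, `qualifier`, `method`,
#'   `locator`, `problem`). Roles left empty are not enforced by
#'   [composeObservation()].
#' @return an [OntologyGraph-class].
#' @export
ontologyGraph <- function(roles = list()) {
  new("OntologyGraph", concepts = emptyConcepts(), edges = emptyEdges(),
      roles = roles)
}

#' Register a concept in a graph
#'
#' Registration is idempotent on the concept key: re-adding a key already
#' present leaves the graph unchanged (table loaders may re-read shared
#' concepts, and distinct table rows may legitimately resolve to the same
#' SNOMED concept).
#'
#' @param graph an [OntologyGraph-class].
#' @param concept a [ConceptRef-class], or a list of them.
#' @return the updated graph.
#' @export
addConcept <- function(graph, concept) {
  if (is.list(concept)) {
    for (c1 in concept) graph <- addConcept(graph, c1)
    return(graph)
  }
  validObject(concept)
  key <- conceptKey(concept)
  if (key %in% graph@concepts$key) return(graph)
  graph@concepts <- rbind(graph@concepts, data.frame(
    key = key, code = concept@code, namespace = concept@namespace,
    designation = concept@designation, axis = concept@axis,
    approximate = concept@approximate, stringsAsFactors = FALSE))
  graph
}

#' Look up concepts in a graph
#'
#' @param graph an [OntologyGraph-class].
#' @param key concept key(s) (`"namespace:code"`), or a [ConceptRef-class].
#' @return `conceptAt`: the [ConceptRef-class] for one key;
#'   `concepts`: the full concept table.
#' @export
conceptAt <- function(graph, key) {
  key <- conceptKey(key)
  i <- match(key, graph@concepts$key)
  if (is.na(i)) apMissingConcept(key)
  row <- graph@concepts[i, ]
  new("ConceptRef", code = row$code, namespace = row$namespace,
      designation = row$designation, axis = row$axis,
      approximate = row$approximate)
}

#' @rdname conceptAt
#' @export
concepts <- function(graph) graph@concepts

#' Resolve a concept by key or designation
#'
#' Accepts a [ConceptRef-class] (checked for registration), a concept key
#' (`"namespace:code"`), or a designation looked up case-insensitively in
#' the graph's concept table.
#'
#' @inheritParams conceptAt
#' @param x concept reference, key or designation.
#' @return a registered [ConceptRef-class].
#' @export
resolveConcept <- function(graph, x) {
  if (is(x, "ConceptRef")) return(conceptAt(graph, conceptKey(x)))
  x <- as.character(x)
  if (grepl(":", x, fixed = TRUE) && x %in% graph@concepts$key)
    return(conceptAt(graph, x))
  hit <- which(graph@concepts$designation == x)
  if (!length(hit))
    hit <- which(tolower(graph@concepts$designation) == tolower(x))
  if (length(hit) == 1L) return(conceptAt(graph, graph@concepts$key[hit]))
  if (length(hit) > 1L)
    apAbort(sprintf("designation '%s' is ambiguous (%s)", x,
                    paste(graph@concepts$key[hit], collapse = ", ")),
            "apMissingConceptError")
  apMissingConcept(x)
}

## parent adjacency as a named list child -> character vector of parents
.parentsOf <- function(edges, type) {
  e <- edges[edges$type == type, , drop = FALSE]
  split(e$parent, factor(e$child, levels = unique(e$child)))
}

## reflexive-transitive reachability from `start` following child -> parent
.reach <- function(edges, type, start) {
  e <- edges[edges$type == type, , drop = FALSE]
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(e$parent[e$child %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  sort(seen, method = "radix")
}

## TRUE if the (child, parent) edge set contains a directed cycle
.hasCycle <- function(e) {
  if (!nrow(e)) return(FALSE)
  # peel sink nodes (no outgoing child -> parent edge); a cycle survives
  repeat {
    nodes <- unique(c(e$child, e$parent))
    sinks <- setdiff(nodes, e$child)
    if (!length(sinks)) return(TRUE)
    e <- e[!(e$parent %in% sinks), , drop = FALSE]
    if (!nrow(e)) return(FALSE)
  }
}

## shortest child -> parent path from `from` up to `to`, as a key vector
.pathUp <- function(edges, type, from, to) {
  e <- edges[edges$type == type, , drop = FALSE]
  prev <- stats::setNames(character(1), from)[0]
  frontier <- from
  seen <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (f in frontier) {
      ps <- e$parent[e$child == f]
      ps <- setdiff(ps, seen)
      if (length(ps)) {
        prev[ps] <- f
        nxt <- c(nxt, ps)
        seen <- c(seen, ps)
      }
    }
    if (to %in% seen) break
    frontier <- nxt
  }
  if (!to %in% seen) return(character(0))
  path <- to
  while (path[1] != from) path <- c(prev[[path[1]]], path)
  path
}

#' Add a typed relationship edge
#'
#' Adds the directed edge `child --type--> parent`. Both concepts must be
#' registered. Adding a duplicate edge is a no-op. For `IS_A` and `PART_OF`
#' the edge is refused with a cycle error (naming the offending path) if it
#' would close a directed cycle.
#'
#' @param graph an [OntologyGraph-class].
#' @param child,parent [ConceptRef-class] or concept keys.
#' @param type one of [relationshipTypes()].
#' @return the updated graph.
#' @examples
#' g <- ontologyGraph()
#' g <- addConcept(g, list(conceptRef(designation = "a", namespace = "local"),
#'                         conceptRef(designation = "b", namespace = "local")))
#' g <- addRelation(g, "local:a", "IS_A", "local:b")
#' @rdname addRelation
#' @export
setMethod("addRelation", "OntologyGraph", function(graph, child, type, parent) {
  stopifnot(type %in% relationshipTypes())
  ck <- conceptKey(child)
  pk <- conceptKey(parent)
  for (k in c(ck, pk)) if (!k %in% graph@concepts$key) apMissingConcept(k)
  dup <- graph@edges$child == ck & graph@edges$type == type &
    graph@edges$parent == pk
  if (any(dup)) return(graph)
  if (type %in% c("IS_A", "PART_OF")) {
    if (ck == pk) apCycle(c(ck, pk))
    # a path parent ->* child already existing would be closed into a cycle
    up <- .reach(graph@edges, type, pk)
    if (ck %in% up) {
      path <- .pathUp(graph@edges, type, pk, ck)
      apCycle(c(ck, path))
    }
  }
  graph@edges <- rbind(graph@edges, data.frame(
    child = ck, type = type, parent = pk, stringsAsFactors = FALSE))
  graph
})

#' Reflexive-transitive closure along one relationship type
#'
#' Follows edges from child to parent, so for `IS_A` the closure of a
#' concept is itself plus all its ancestors. Returned keys are sorted, so
#' the result is a deterministic set.
#'
#' @param graph an [OntologyGraph-class].
#' @param concept [ConceptRef-class] or concept key.
#' @param type one of [relationshipTypes()].
#' @return sorted character vector of concept keys.
#' @rdname conceptClosure
#' @export
setMethod("conceptClosure", "OntologyGraph", function(graph, concept, type = "IS_A") {
  stopifnot(type %in% relationshipTypes())
  k <- conceptKey(concept)
  if (!k %in% graph@concepts$key) apMissingConcept(k)
  .reach(graph@edges, type, k)
})

#' Permissible-value test with descendant closure
#'
#' A candidate concept is a permissible value for a role root when the root
#' is among the candidate's `IS_A` ancestors, the root itself included
#' ("permissible values, their descendants included").
#'
#' @param graph an [OntologyGraph-class].
#' @param candidate,roleRoot [ConceptRef-class] or concept keys.
#' @return logical(1).
#' @rdname isPermissible
#' @export
setMethod("isPermissible", "OntologyGraph", function(graph, candidate, roleRoot) {
  rk <- conceptKey(roleRoot)
  if (!rk %in% graph@concepts$key) apMissingConcept(rk)
  rk %in% conceptClosure(graph, candidate, "IS_A")
})

#' Edge table for one relationship type
#'
#' `inverse = TRUE` returns the inverse view: for `HAS_TARGET` this is the
#' `IS-TARGET-OF` reading (targets on the left, properties on the right).
#' The inverse is a view only; no inverse edges are ever stored.
#'
#' @param graph an [OntologyGraph-class].
#' @param type one of [relationshipTypes()].
#' @param inverse flip edge direction in the returned table.
#' @return data.frame with columns `child`, `type`, `parent`.
#' @export
relationTable <- function(graph, type, inverse = FALSE) {
  stopifnot(type %in% relationshipTypes())
  e <- graph@edges[graph@edges$type == type, , drop = FALSE]
  rownames(e) <- NULL
  if (!inverse) return(e)
  inv <- data.frame(child = e$parent,
                    type = if (type == "HAS_TARGET") "IS_TARGET_OF" else
                      paste0("INVERSE_", type),
                    parent = e$child, stringsAsFactors = FALSE)
  inv
}

#' Structural signature of a graph
#'
#' Used to detect comparisons between expressions validated against
#' different graphs.
#' @keywords internal
graphSignature <- function(graph) {
  paste(
    paste(sort(graph@concepts$key), collapse = ","),
    paste(sort(paste(graph@edges$child, graph@edges$type, graph@edges$parent)),
          collapse = ","),
    sep = ";"
  )
}

setMethod("show", "ConceptRef", function(object) {
  cat(sprintf("<ConceptRef> %s [%s]%s%s\n", object@designation,
              conceptKey(object),
              if (!is.na(object@axis)) sprintf(" (%s)", object@axis) else "",
              if (object@approximate) " ~approximate" else ""))
})

setMethod("show", "OntologyGraph", function(object) {
  cat(sprintf("OntologyGraph: %d concepts, %d edges (%s)\n",
              nrow(object@concepts), nrow(object@edges),
              paste(sprintf("%s: %d", relationshipTypes(),
                            vapply(relationshipTypes(), function(t)
                              sum(object@edges$type == t), integer(1))),
                    collapse = ", ")))
  if (length(object@roles))
    cat("  roles:", paste(sprintf("%s (%d roots)", names(object@roles),
                                  lengths(object@roles)), collapse = ", "), "\n")
})
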