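# shared fixtures, built once per test run

refGraph <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- buildReferenceOntology()
    g
  }
})

refEq <- local({
  eq <- NULL
  function() {
    if (is.null(eq)) eq <<- loadEquivalenceTable()
    eq
  }
})

# a tiny free graph (no role restrictions) with named local concepts
tinyGraph <- function(labels) {
  g <- ontologyGraph()
  for (l in labels)
    g <- addConcept(g, conceptRef(designation = l, namespace = "local"))
  g
}

lkey <- function(label) paste0("local:", gsub("[^a-z0-9]+", "-", tolower(label)))

# random DAG over n nodes: only edges j -> i with i < j, so acyclic by
# construction; returns the graph plus its edge list
randomDAG <- function(n, p = 0.1, type = "IS_A") {
  labels <- sprintf("n%02d", seq_len(n))
  g <- tinyGraph(labels)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      if (stats::runif(1) < p)
        g <- addRelation(g, lkey(labels[j]), type, lkey(labels[i]))
    }
  }
  g
}

# brute-force closure oracle: enumerate every child -> parent path by
# unmemoized depth-first search
oracleClosure <- function(graph, start, type) {
  e <- relationTable(graph, type)
  visit <- function(node) {
    parents <- e$parent[e$child == node]
    unique(c(node, unlist(lapply(parents, visit))))
  }
  sort(visit(conceptKey(start)), method = "radix")
}

# slot-wise subsumption oracle built on the brute-force closure
oracleSubsumes <- function(a, b, graph) {
  anc <- function(key) oracleClosure(graph, key, "IS_A")
  slotOK <- function(sa, sb) {
    if (is.null(sa)) return(TRUE)
    if (is.null(sb)) return(FALSE)
    conceptKey(sa) %in% anc(conceptKey(sb))
  }
  if (!slotOK(a@target, b@target)) return(FALSE)
  if (!slotOK(a@property, b@property)) return(FALSE)
  if (!slotOK(a@context@locator, b@context@locator)) return(FALSE)
  if (!slotOK(a@context@problem, b@context@problem)) return(FALSE)
  if (!slotOK(a@context@method, b@context@method)) return(FALSE)
  all(vapply(a@qualifiers, function(qa)
    any(vapply(b@qualifiers, function(qb)
      conceptKey(qa) %in% anc(conceptKey(qb)), logical(1))),
    logical(1)))
}

# random valid expression over the reference ontology
randomExpression <- function(g = refGraph()) {
  pick <- function(keys) conceptAt(g, sample(keys, 1))
  roles <- g@roles
  qualPool <- c("local:nearest", "local:biggest", "local:most", "local:least",
                "local:smallest", "local:largest", "snomed:272741003",
                "snomed:10179008", "local:focality")
  nq <- sample(0:3, 1)
  organs <- paste0("local:", gsub("[^a-z0-9]+", "-", tolower(defaultOrgans())))
  problems <- c("local:invasive-tumor", "local:non-invasive-tumor",
                "local:non-neoplastic-problem")
  methods <- c("local:observedbymicroscopicinvestigation",
               "local:observedbymacroscopicinvestigation",
               "local:observedbymolecularinvestigation")
  value <- switch(sample(3, 1),
                  NULL,
                  obsValue(magnitude = round(stats::runif(1, 0.1, 99), 2),
                           unit = sample(c("mm", "g", "1"), 1)),
                  obsValue(coded = pick(qualPool)))
  composeObservation(
    g,
    target = pick(roles$target),
    property = pick(roles$property),
    qualifiers = if (nq) lapply(sample(qualPool, nq), conceptAt, graph = g)
                 else list(),
    context = obsContext(
      locator = if (stats::runif(1) < 0.6) pick(organs),
      problem = if (stats::runif(1) < 0.6) pick(problems),
      method = if (stats::runif(1) < 0.5) pick(methods)),
    value = value)
}

expectObsEqual <- function(a, b) {
  expect_identical(observationKey(a), observationKey(b))
}
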