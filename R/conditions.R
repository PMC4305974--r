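#' @keywords internal
apAbort <- function(msg, class, data = list()) {
  cond <- structure(
    class = c(class, "aptermsError", "error", "condition"),
    c(list(message = msg, call = NULL), data)
  )
  stop(cond)
}

apMissingConcept <- function(key) {
  apAbort(sprintf("concept not registered in graph: %s", key),
          "apMissingConceptError", list(key = key))
}

apCycle <- function(path) {
  apAbort(sprintf("relation would create a cycle: %s", paste(path, collapse = " -> ")),
          "apCycleError", list(path = path))
}

apConstraint <- function(msgs) {
  apAbort(paste0("expression violates role constraints:\n",
                 paste0("  - ", msgs, collapse = "\n")),
          "apConstraintError", list(violations = msgs))
}

apParse <- function(msg) apAbort(msg, "apParseError")
apDialect <- function(msg) apAbort(msg, "apDialectError")
apNotFound <- function(msg) apAbort(msg, "apNotFoundError")
apConfig <- function(msg) apAbort(msg, "apConfigError")
apGraphMismatch <- function(msg) apAbort(msg, "apGraphMismatchError")
apCoverageUndefined <- function() {
  apAbort("SNOMED coverage is undefined for an empty concept collection",
          "apCoverageError")
}
apUsage <- function(msg) apAbort(msg, "apUsageError")
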