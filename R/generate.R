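## run fn with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, fn) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic precoordinated registry
#'
#' Emits exactly the profiled number of templates per family. Generic-family
#' templates are expansions of the recipe catalog over `(organ, problem)`
#' contexts: core-generic recipes cover every organ (problems alternating),
#' the other families draw their contexts from the organ-by-problem grid
#' with the profile's seeded RNG. Generic templates carry the recipe's
#' context-invariant value set; specific templates re-use one base value set
#' but get one perturbed context (an extra member), so the value-set-
#' uniqueness criterion separates the two groups; procedure templates are
#' context-free. Context-bearing names follow the `Organ-Problem-Element`
#' grammar; OIDs are allocated sequentially under the profile's reserved
#' branch. The output is deterministic for a fixed profile and seed, and the
#' family counts are deterministic for any seed.
#'
#' @param profile a [CompositionProfile-class].
#' @param eq an [EquivalenceTable-class] supplying the recipe catalog.
#' @param graph the reference [OntologyGraph-class]; every recipe concept
#'   must resolve against it (configuration error otherwise).
#' @return registry data.frame (columns oid, name, organ, problem, category,
#'   list-column value_set).
#' @examples
#' \donttest{
#' reg <- generateRegistry(defaultProfile(seed = 1))
#' nrow(reg)
#' }
#' @export
generateRegistry <- function(profile, eq = loadEquivalenceTable(),
                             graph = buildReferenceOntology()) {
  validObject(profile)

  # every recipe must resolve against the ontology before anything is emitted
  for (i in seq_len(nrow(eq@recipes))) {
    for (what in c("target", "property")) {
      x <- eq@recipes[[what]][i]
      tryCatch(resolveConcept(graph, x), aptermsError = function(e)
        apConfig(sprintf("recipe '%s' references unknown %s concept '%s'",
                         eq@recipes$designation[i], what, x)))
    }
    q <- eq@recipes$qualifiers[i]
    if (nzchar(q %||% "")) {
      for (x in strsplit(q, "|", fixed = TRUE)[[1]])
        tryCatch(resolveConcept(graph, x), aptermsError = function(e)
          apConfig(sprintf("recipe '%s' references unknown qualifier '%s'",
                           eq@recipes$designation[i], x)))
    }
  }

  grid <- expand.grid(organ = profile@organs, problem = profile@problems,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  rows <- list()
  emit <- function(name, organ, problem, category, vs, source) {
    rows[[length(rows) + 1L]] <<- list(name = name, organ = organ,
                                       problem = problem, category = category,
                                       value_set = vs, source = source)
  }

  .withSeed(profile@seed, function() {
    for (fam in names(profile@contextsPerFamily)) {
      k <- profile@contextsPerFamily[[fam]]
      if (k <= 0) next
      rec <- eq@recipes[eq@recipes$family == fam, , drop = FALSE]
      for (i in seq_len(nrow(rec))) {
        vs <- if (nzchar(rec$value_set[i]))
          strsplit(rec$value_set[i], "|", fixed = TRUE)[[1]] else character(0)
        ctxIdx <- if (identical(fam, "core_generic")) {
          # cycle through the organs so all of them are covered;
          # problems alternate by organ and recipe index
          vapply(seq_len(k), function(j) {
            o <- (j - 1L) %% length(profile@organs) + 1L
            p <- (o + i) %% length(profile@problems) + 1L
            which(grid$organ == profile@organs[o] &
                    grid$problem == profile@problems[p])[1]
          }, integer(1))
        } else {
          sample(nrow(grid), min(k, nrow(grid)))
        }
        for (ci in ctxIdx) {
          emit(paste(grid$organ[ci], grid$problem[ci], rec$pattern[i],
                     sep = "-"),
               grid$organ[ci], grid$problem[ci], "observation", vs,
               rec$designation[i])
        }
      }
    }
    # specific templates: same element in several contexts, one perturbed
    for (j in seq_along(profile@specificElements)) {
      k <- profile@specificOccurrences[j]
      if (k <= 0) next
      ctxIdx <- sample(nrow(grid), min(k, nrow(grid)))
      for (m in seq_along(ctxIdx)) {
        ci <- ctxIdx[m]
        vs <- profile@specificValueSet
        if (m == 1L) vs <- c(vs, "focal variant")
        emit(paste(grid$organ[ci], grid$problem[ci],
                   profile@specificElements[j], sep = "-"),
             grid$organ[ci], grid$problem[ci], "observation", vs,
             NA_character_)
      }
    }
    for (nm in profile@procedureNames)
      emit(nm, NA_character_, NA_character_, "procedure", character(0),
           NA_character_)
  })

  n <- length(rows)
  if (!n) {
    out <- emptyRegistry()
    attr(out, "sources") <- character(0)
    attr(out, "skipped") <- data.frame(row = integer(), oid = character(),
                                       reason = character(),
                                       stringsAsFactors = FALSE)
    return(out)
  }
  out <- data.frame(
    oid = paste0(profile@oidBranch, ".", seq_len(n)),
    name = vapply(rows, `[[`, character(1), "name"),
    organ = vapply(rows, `[[`, character(1), "organ"),
    problem = vapply(rows, `[[`, character(1), "problem"),
    category = vapply(rows, `[[`, character(1), "category"),
    stringsAsFactors = FALSE)
  out$value_set <- lapply(rows, `[[`, "value_set")
  # sidecar for round-trip testing: which recipe produced each row (NA for
  # specific and procedure templates); the decomposer never reads this
  attr(out, "sources") <- vapply(rows, `[[`, character(1), "source")
  attr(out, "skipped") <- data.frame(row = integer(), oid = character(),
                                     reason = character(),
                                     stringsAsFactors = FALSE)
  out
}
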