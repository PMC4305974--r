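test_that("template names parse into organ, problem and element", {
  p <- parseName("Breast-In situ neoplasm-Lesion size, largest dimension")
  expect_identical(p$organ, "Breast")
  expect_identical(p$problem, "In situ neoplasm")
  expect_identical(p$element, "Lesion size, largest dimension")

  p2 <- parseName("Specimen weight")
  expect_true(is.na(p2$organ) && is.na(p2$problem))
  expect_identical(p2$element, "Specimen weight")

  # hyphens inside element names are not delimiters unless an organ leads
  expect_identical(parseName("Ki-67")$element, "Ki-67")
  expect_identical(parseName("Breast-Invasive neoplasm-Ki-67")$element, "Ki-67")
  expect_identical(parseName("Lymph node-Invasive neoplasm-CD20")$organ,
                   "Lymph node")

  expect_error(parseName(""), class = "apParseError")
  expect_error(parseName("---"), class = "apParseError")
})

test_that("the breast worked example decomposes to the published expression", {
  g <- refGraph(); eq <- refEq()
  term <- precoordinatedTerm(
    "1.3.6.1.4.1.49376.1.8.1.4.442",
    "Breast-In situ neoplasm-Lesion size, largest dimension")
  res <- decomposeTerm(term, eq, g)
  expect_identical(res@verdict, "generic")
  expect_identical(res@matchedGenericElement, "Diameter")
  e <- res@expression
  expect_identical(e@property@designation, "Diameter")
  expect_identical(e@target@designation, "Lesion")
  quals <- tolower(c(e@context@method@designation,
                     vapply(e@qualifiers, function(q) q@designation,
                            character(1))))
  expect_setequal(quals, c("observedbymicroscopicinvestigation", "largest"))
  expect_identical(e@context@locator@designation, "Breast")
  expect_identical(e@context@problem@designation, "non-invasive tumor")
})

test_that("context-free and unmatched terms decompose as published", {
  g <- refGraph(); eq <- refEq()
  w <- decomposeTerm(precoordinatedTerm("1.3.6.1.4.1.19376.1.8.1.4.160",
                                        "Specimen weight"), eq, g)
  expect_identical(w@verdict, "generic")
  expect_identical(w@matchedGenericElement, "Weight")
  expect_identical(w@expression@property@designation, "Weight")
  expect_identical(w@expression@target@designation, "Specimen")

  s <- decomposeTerm(precoordinatedTerm("1.2.3.4",
                                        "Liver-Invasive neoplasm-ZZZ unknown feature"),
                     eq, g)
  expect_identical(s@verdict, "specific")
  expect_null(s@expression)
  expect_match(s@unmatchedReason, "ZZZ unknown feature")

  p <- decomposeTerm(precoordinatedTerm("1.2.3.5", "Frozen section preparation",
                                        category = "procedure"), eq, g)
  expect_identical(p@verdict, "procedure")
})

test_that("a recipe referencing an unregistered concept is a configuration error", {
  g <- refGraph(); eq <- refEq()
  eq@recipes$target[eq@recipes$designation == "Weight"] <- "Klingon artifact"
  expect_error(
    decomposeTerm(precoordinatedTerm("1.2.3", "Specimen weight"), eq, g),
    class = "apConfigError")
})

test_that("value-set uniqueness separates generic from specific elements", {
  mk <- function(names, vsets) {
    reg <- data.frame(oid = paste0("1.2.", seq_along(names)), name = names,
                      organ = NA, problem = NA, category = "observation",
                      stringsAsFactors = FALSE)
    reg$value_set <- vsets
    reg
  }
  reg <- mk(c("Breast-Invasive neoplasm-Extent",
              "Colon-Invasive neoplasm-Extent",
              "Lung-In situ neoplasm-Extent",
              "Breast-Invasive neoplasm-Oddity",
              "Colon-Invasive neoplasm-Oddity",
              "Solo finding"),
            list(c("limited", "extensive"),
                 c("extensive", "limited"),     # order-insensitive
                 c("limited", "extensive"),
                 c("absent", "present"),
                 c("absent", "present", "focal"),
                 c("yes", "no")))
  expect_identical(classifyGenericity("Extent", reg), "generic")
  expect_identical(classifyGenericity("Oddity", reg), "specific")
  # single occurrence: vacuously generic, invertible by policy
  expect_identical(classifyGenericity("Solo finding", reg), "generic")
  expect_identical(classifyGenericity("Solo finding", reg, strictSingle = TRUE),
                   "specific")
  expect_error(classifyGenericity("Never seen", reg), class = "apNotFoundError")

  # permutation invariance in registry order
  perm <- sample(nrow(reg))
  reg2 <- reg[perm, , drop = FALSE]
  reg2$value_set <- reg$value_set[perm]
  expect_identical(classifyGenericity("Extent", reg2), "generic")
  expect_identical(classifyGenericity("Oddity", reg2), "specific")
})

test_that("SNOMED coverage counts approximate codes and de-duplicates", {
  allCoded <- list(conceptRef("1", "a"), conceptRef("2", "b"))
  expect_identical(snomedCoverage(allCoded), 100)
  noneCoded <- list(conceptRef(designation = "x", namespace = "local"),
                    conceptRef(designation = "y", namespace = "local"))
  expect_identical(snomedCoverage(noneCoded), 0)
  expect_error(snomedCoverage(list()), class = "apCoverageError")

  tables <- c(loadValueSetTable("targets.tsv"),
              loadValueSetTable("properties.tsv"),
              loadValueSetTable("qualifiers.tsv"))
  expect_identical(snomedCoverage(tables), 94.9)
  # duplicating rows does not change the figure
  expect_identical(snomedCoverage(c(tables, tables)), 94.9)
})

test_that("an empty registry produces an all-zero report", {
  g <- refGraph(); eq <- refEq()
  reg <- generateRegistry(
    compositionProfile(contextsPerFamily = c(core_generic = 0,
                                             staging_grading_classification = 0,
                                             marker = 0,
                                             unclassified_generic = 0)),
    eq, g)
  expect_identical(nrow(reg), 0L)
  st <- registryStats(reg, eq, g)
  expect_identical(st@totalTemplates, 0)
  expect_identical(st@genericElements, 0)
  expect_identical(st@organs, 0)
})

test_that("registry statistics agree with an independent recount", {
  g <- refGraph(); eq <- refEq()
  set.seed(77)
  for (rep in 1:3) {
    prof <- compositionProfile(
      contextsPerFamily = c(core_generic = sample(1:4, 1),
                            staging_grading_classification = sample(0:3, 1),
                            marker = sample(0:2, 1),
                            unclassified_generic = sample(0:1, 1)),
      specificElements = c("Quirk A", "Quirk B"),
      specificOccurrences = sample(2:3, 2, replace = TRUE),
      procedureNames = paste("Procedure", 1:sample(1:4, 1)),
      seed = rep)
    reg <- generateRegistry(prof, eq, g)
    st <- registryStats(reg, eq, g)

    # brute-force recount straight from per-term decompositions
    verdicts <- vapply(seq_len(nrow(reg)), function(i)
      decomposeTerm(reg[i, , drop = FALSE], eq, g)@verdict, character(1))
    expect_identical(st@totalTemplates, nrow(reg))
    expect_identical(st@procedures, sum(verdicts == "procedure"))
    expect_identical(st@observations, sum(verdicts != "procedure"))
    expect_identical(st@genericMapped, sum(verdicts == "generic"))
    expect_identical(st@specificTerms, sum(verdicts == "specific"))
    # conservation invariants
    expect_identical(st@observations + st@procedures, st@totalTemplates)
    expect_identical(st@genericMapped + st@specificTerms, st@observations)
    expect_true(st@stagingGradingClassificationTerms + st@markerTerms +
                  st@coreGenericTerms <= st@genericElements)
  }
})
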