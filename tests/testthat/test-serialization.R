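test_that("compositional-grammar rendering is deterministic and code-faithful", {
  g <- refGraph()
  w <- composeObservation(g, "Specimen", "Weight")
  s <- toSCG(w)
  expect_match(tolower(s), "^123038009 \\|specimen\\| : 272102008 \\|weight\\|$")
  expect_identical(toSCG(w), s)

  breast <- composeObservation(
    g, "Lesion", "Diameter", qualifiers = list("largest"),
    context = obsContext(locator = resolveConcept(g, "Breast"),
                         problem = resolveConcept(g, "non-invasive tumor"),
                         method = resolveConcept(
                           g, "ObservedByMicroscopicInvestigation")))
  sb <- toSCG(breast)
  expect_match(sb, "49755003")
  expect_match(sb, "81827009")
  expect_match(sb, "ap:", fixed = TRUE)  # local concepts carry the prefix
})

test_that("SCG, JSON and XML round trips preserve canonical equality", {
  g <- refGraph()
  set.seed(300)
  for (i in 1:25) {
    e <- randomExpression(g)
    expectObsEqual(parseSCG(toSCG(e), g), e)
    expectObsEqual(expressionFromJSON(expressionToJSON(e), g), e)
    expectObsEqual(readExpressionXML(writeExpressionXML(e), g), e)
  }
})

test_that("SCG parse errors are reported for malformed input", {
  g <- refGraph()
  expect_error(parseSCG("", g), class = "apParseError")
  expect_error(parseSCG("garbage without pipes", g), class = "apParseError")
  # a focus without property refinement is not a valid expression
  expect_error(parseSCG("123038009 |Specimen|", g), class = "apParseError")
})

test_that("XML output is byte-stable, schema-valid and relationship-coded", {
  g <- refGraph()
  w <- composeObservation(g, "Specimen", "Weight",
                          value = obsValue(magnitude = 34.5, unit = "g"))
  x1 <- writeExpressionXML(w)
  x2 <- writeExpressionXML(w)
  expect_identical(x1, x2)
  expect_true(validateExpressionXML(x1))

  doc <- xml2::xml_ns_strip(xml2::read_xml(x1))
  prop <- xml2::xml_find_first(doc, "./property")
  expect_identical(xml2::xml_attr(prop, "relationship"), "HAS-TARGET")

  q <- composeObservation(g, "Lesion", "Diameter", qualifiers = list("largest"))
  xq <- writeExpressionXML(q)
  expect_true(validateExpressionXML(xq))
  qn <- xml2::xml_find_first(xml2::xml_ns_strip(xml2::read_xml(xq)),
                             "./qualifier")
  expect_identical(xml2::xml_attr(qn, "relationship"), "IS-QUALIFIER-OF")

  set.seed(301)
  for (i in 1:10) expect_true(validateExpressionXML(
    writeExpressionXML(randomExpression(g))))
})

test_that("approximate codes survive the XML round trip", {
  g <- refGraph()
  e <- composeObservation(g, "Lesion", "NeighborhoodRelationship")
  x <- writeExpressionXML(e)
  expect_match(x, 'approximate="true"', fixed = TRUE)
  e2 <- readExpressionXML(x, g)
  expect_true(e2@property@approximate)
})

test_that("registries survive a write/read round trip", {
  g <- refGraph()
  reg <- generateRegistry(
    compositionProfile(
      specificElements = "Odd local finding", specificOccurrences = 2,
      procedureNames = c("Specimen photography", "Gross sectioning"),
      contextsPerFamily = c(core_generic = 2,
                            staging_grading_classification = 1,
                            marker = 1, unclassified_generic = 1),
      seed = 5),
    refEq(), g)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRegistry(reg, path)
  back <- readRegistry(path)
  expect_identical(back$oid, reg$oid)
  expect_identical(back$name, reg$name)
  expect_identical(back$organ, reg$organ)
  expect_identical(back$problem, reg$problem)
  expect_identical(back$category, reg$category)
  expect_identical(back$value_set, reg$value_set)
  expect_identical(nrow(attr(back, "skipped")), 0L)
})

test_that("rows with malformed OIDs are excluded but reported", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "oid\tname\torgan\tproblem\tcategory\tvalue_set",
    "1.2.3.4\tSpecimen weight\t\t\tobservation\t",
    "not.an..oid\tBroken row\t\t\tobservation\ta|b",
    "1.2.3.5\t\t\t\tobservation\t",
    "1.2.3.6\tOdd category\t\t\tsurvey\t"), path)
  reg <- readRegistry(path)
  expect_identical(nrow(reg), 1L)
  skipped <- attr(reg, "skipped")
  expect_identical(nrow(skipped), 3L)
  expect_setequal(skipped$reason,
                  c("malformed OID", "empty name", "unknown category"))
})

test_that("dialect violations are reported as such", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("oid\tname\torgan", "1.2.3\tx\ty"), path)
  expect_error(readRegistry(path), class = "apDialectError")
  expect_error(readRegistry(file.path(tempdir(), "no-such-registry.tsv")),
               class = "aptermsError")
})
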