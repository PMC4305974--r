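test_that("the worked breast example composes into a valid expression", {
  g <- refGraph()
  expr <- composeObservation(
    g, target = "Lesion", property = "Diameter",
    qualifiers = list("largest"),
    context = obsContext(locator = resolveConcept(g, "Breast"),
                         problem = resolveConcept(g, "non-invasive tumor"),
                         method = resolveConcept(
                           g, "ObservedByMicroscopicInvestigation")))
  expect_s4_class(expr, "GenericObservation")
  expect_identical(expr@target@code, "49755003")
  expect_identical(expr@property@code, "81827009")
  expect_identical(expr@context@locator@designation, "Breast")
  expect_identical(expr@context@problem@designation, "non-invasive tumor")
})

test_that("a context-free specimen-weight expression is valid", {
  g <- refGraph()
  expr <- composeObservation(g, target = "Specimen", property = "Weight")
  expect_identical(expr@target@code, "123038009")
  expect_identical(expr@property@code, "272102008")
  expect_null(expr@context@locator)
  expect_null(expr@context@problem)
})

test_that("role violations raise one aggregated constraint error", {
  g <- refGraph()
  # a target concept in the property role
  err <- tryCatch(composeObservation(g, target = "Specimen", property = "Lesion"),
                  apConstraintError = function(e) e)
  expect_s3_class(err, "apConstraintError")
  expect_match(conditionMessage(err), "property")
  expect_match(conditionMessage(err), "Lesion")

  # several violations reported together, not first-failure
  err2 <- tryCatch(
    composeObservation(g, target = "Diameter", property = "Lesion",
                       qualifiers = list("Specimen")),
    apConstraintError = function(e) e)
  expect_length(err2$violations, 3L)
  expect_match(conditionMessage(err2), "target")
  expect_match(conditionMessage(err2), "qualifier")
})

test_that("qualifiers are canonicalized: deduplicated and order-insensitive", {
  g <- refGraph()
  e1 <- composeObservation(g, "Lesion", "Diameter",
                           qualifiers = list("largest", "nearest", "largest"))
  e2 <- composeObservation(g, "Lesion", "Diameter",
                           qualifiers = list("nearest", "largest"))
  expect_identical(observationKey(e1), observationKey(e2))
  expect_length(e1@qualifiers, 2L)
  keys <- vapply(e1@qualifiers, conceptKey, character(1))
  expect_identical(keys, sort(keys, method = "radix"))
})

test_that("quantity and coded values validate their invariants", {
  expect_error(obsValue(), "exactly one of coded value or quantity")
  expect_error(validObject(obsValue(magnitude = Inf, unit = "mm")))
  expect_error(validObject(new("ObservationValue", coded = NULL,
                               magnitude = 3.5, unit = character(0))))
  v <- obsValue(magnitude = 3.5, unit = "mm")
  expect_identical(v@unit, "mm")
})

test_that("subsumption is reflexive and dropping qualifiers generalizes", {
  g <- refGraph()
  b <- composeObservation(g, "Lesion", "Diameter", qualifiers = list("largest"))
  a <- composeObservation(g, "Lesion", "Diameter")
  expect_true(subsumes(b, b, g))
  expect_true(subsumes(a, b, g))
  expect_false(subsumes(b, a, g))
})

test_that("absent context slots in the subsumer match anything", {
  g <- refGraph()
  b <- composeObservation(g, "Lesion", "Diameter",
                          context = obsContext(
                            locator = resolveConcept(g, "Breast"),
                            problem = resolveConcept(g, "invasive tumor")))
  a <- composeObservation(g, "Lesion", "Diameter")
  expect_true(subsumes(a, b, g))
  expect_false(subsumes(b, a, g))
})

test_that("expressions from different graphs are refused", {
  g <- refGraph()
  e1 <- composeObservation(g, "Lesion", "Diameter")
  g2 <- addConcept(g, conceptRef(designation = "other", namespace = "local"))
  e2 <- composeObservation(g2, "Lesion", "Diameter")
  expect_error(subsumes(e1, e2, g), class = "apGraphMismatchError")
})

test_that("subsumption matches the slot-wise oracle and is a preorder", {
  g <- refGraph()
  set.seed(90)
  exprs <- replicate(12, randomExpression(g), simplify = FALSE)
  for (a in exprs) {
    expect_true(subsumes(a, a, g))  # reflexivity
    for (b in exprs) {
      expect_identical(subsumes(a, b, g), oracleSubsumes(a, b, g),
                       info = paste(observationKey(a), "vs", observationKey(b)))
    }
  }
  # transitivity on all triples
  m <- outer(seq_along(exprs), seq_along(exprs),
             Vectorize(function(i, j) subsumes(exprs[[i]], exprs[[j]], g)))
  for (i in seq_along(exprs)) for (j in seq_along(exprs))
    for (k in seq_along(exprs))
      if (m[i, j] && m[j, k]) expect_true(m[i, k])
})

test_that("every composed expression has table-backed target and property roles", {
  g <- refGraph()
  set.seed(91)
  targetRoots <- g@roles$target
  propertyRoots <- g@roles$property
  for (i in 1:20) {
    e <- randomExpression(g)
    expect_true(any(targetRoots %in% conceptClosure(g, e@target, "IS_A")))
    expect_true(any(propertyRoots %in% conceptClosure(g, e@property, "IS_A")))
  }
})
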