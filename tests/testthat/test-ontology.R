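test_that("relations can be added, are idempotent, and report unknown concepts", {
  g <- tinyGraph(c("Nucleus", "cell structure root"))
  g <- addRelation(g, lkey("Nucleus"), "IS_A", lkey("cell structure root"))
  expect_true(lkey("cell structure root") %in%
                conceptClosure(g, lkey("Nucleus"), "IS_A"))

  # duplicate insertion leaves the graph unchanged
  g2 <- addRelation(g, lkey("Nucleus"), "IS_A", lkey("cell structure root"))
  expect_identical(g2@edges, g@edges)

  expect_error(addRelation(g, "local:ghost", "IS_A", lkey("Nucleus")),
               class = "apMissingConceptError")
  expect_error(conceptClosure(g, "local:ghost", "IS_A"),
               class = "apMissingConceptError")
})

test_that("IS_A and PART_OF cycles are refused and the path is named", {
  for (tp in c("IS_A", "PART_OF")) {
    g <- tinyGraph(c("a", "b", "c"))
    g <- addRelation(g, "local:a", tp, "local:b")
    err <- tryCatch(addRelation(g, "local:b", tp, "local:a"),
                    apCycleError = function(e) e)
    expect_s3_class(err, "apCycleError")
    expect_match(conditionMessage(err), "local:a.*local:b", all = FALSE)

    # longer cycle through an intermediate node
    g <- addRelation(g, "local:b", tp, "local:c")
    expect_error(addRelation(g, "local:c", tp, "local:a"),
                 class = "apCycleError")
    # self-loop
    expect_error(addRelation(g, "local:a", tp, "local:a"),
                 class = "apCycleError")
  }
})

test_that("closure is reflexive, transitive, and matches the brute-force oracle", {
  g <- tinyGraph("solo")
  expect_identical(conceptClosure(g, "local:solo", "IS_A"), "local:solo")

  g <- tinyGraph(c("a", "b", "c"))
  g <- addRelation(g, "local:a", "IS_A", "local:b")
  g <- addRelation(g, "local:b", "IS_A", "local:c")
  expect_setequal(conceptClosure(g, "local:a", "IS_A"),
                  c("local:a", "local:b", "local:c"))

  set.seed(402)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    g <- randomDAG(n, p = 0.12)
    for (node in sample(g@concepts$key, 5)) {
      expect_identical(conceptClosure(g, node, "IS_A"),
                       oracleClosure(g, node, "IS_A"))
    }
  }
})

test_that("closure is monotone under edge insertion", {
  set.seed(7)
  g <- randomDAG(15, p = 0.15)
  before <- lapply(g@concepts$key, conceptClosure, graph = g, type = "IS_A")
  # add a few more forward edges (acyclic by construction)
  added <- 0L
  for (j in rev(seq_len(15))) {
    for (i in seq_len(j - 1L)) {
      if (added >= 5L) break
      g2 <- tryCatch(addRelation(g, g@concepts$key[j], "IS_A",
                                 g@concepts$key[i]),
                     apCycleError = function(e) NULL)
      if (!is.null(g2) && nrow(g2@edges) > nrow(g@edges)) {
        g <- g2
        added <- added + 1L
      }
    }
  }
  after <- lapply(g@concepts$key, conceptClosure, graph = g, type = "IS_A")
  for (i in seq_along(before))
    expect_true(all(before[[i]] %in% after[[i]]))
})

test_that("permissibility follows the descendants-included rule", {
  g <- refGraph()
  lesion <- resolveConcept(g, "Lesion")

  # the root itself is permissible
  expect_true(isPermissible(g, lesion, lesion))

  # a registered IS_A child of Lesion is permissible under Lesion
  g2 <- addConcept(g, conceptRef(designation = "Microcalcification",
                                 namespace = "local"))
  g2 <- addRelation(g2, "local:microcalcification", "IS_A", lesion)
  expect_true(isPermissible(g2, "local:microcalcification", lesion))

  # disjoint roots are not permissible values of one another
  expect_false(isPermissible(g, resolveConcept(g, "Weight"),
                             resolveConcept(g, "Specimen")))
})

test_that("permissibility is consistent under subsumption of roots", {
  # x permissible under r implies x permissible under every ancestor of r
  set.seed(11)
  for (rep in 1:3) {
    g <- randomDAG(20, p = 0.15)
    keys <- g@concepts$key
    for (x in sample(keys, 6)) {
      for (r in conceptClosure(g, x, "IS_A")) {
        expect_true(isPermissible(g, x, r))
        for (r2 in conceptClosure(g, r, "IS_A"))
          expect_true(isPermissible(g, x, r2))
      }
    }
  }
})

test_that("IS_TARGET_OF is exposed only as the inverse view of HAS_TARGET", {
  g <- refGraph()
  stored <- relationTable(g, "HAS_TARGET")
  inv <- relationTable(g, "HAS_TARGET", inverse = TRUE)
  expect_identical(inv$child, stored$parent)
  expect_identical(inv$parent, stored$child)
  expect_true(all(inv$type == "IS_TARGET_OF"))
  expect_false("IS_TARGET_OF" %in% g@edges$type)
  # weight has target specimen, hence the inverse view lists specimen -> weight
  expect_true(any(inv$child == "snomed:123038009" &
                    inv$parent == "snomed:272102008"))
})

test_that("concept identity is (namespace, code) and re-registration is a no-op", {
  g <- refGraph()
  # the qualifier table's abnormalStructure row shares the Lesion code
  expect_identical(conceptAt(g, "snomed:49755003")@designation, "Lesion")
  n0 <- nrow(concepts(g))
  g2 <- addConcept(g, conceptRef("49755003", "abnormalStructure"))
  expect_identical(nrow(concepts(g2)), n0)
})
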