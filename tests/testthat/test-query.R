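# Selector algebra, built-in templates, shared targets, provenance.

queryFixture <- function() {
  # 5 proteins, a small is_a hierarchy, one reified interaction
  knowledgeGraph("qf",
    nodes = data.frame(
      id = c(sprintf("UniProtKB:P%d", 1:5), "GO:root", "GO:a", "GO:b",
             "MI:0407", "intact:I1", "NCBITaxon:9606"),
      category = c(rep("protein", 5), rep("ontology_class", 4),
                   "interaction", "taxon")),
    relations = defaultRelations()$relations,
    superRelations = defaultRelations()$superRelations,
    statements = data.frame(
      subject = c("GO:a", "GO:b",
                  "UniProtKB:P1", "UniProtKB:P2", "UniProtKB:P3",
                  "intact:I1", "intact:I1", "intact:I1",
                  "UniProtKB:P1"),
      predicate = c("is_a", "is_a",
                    "participates_in", "participates_in",
                    "participates_in",
                    "has_participant", "has_participant",
                    "has_interaction_type",
                    "in_taxon"),
      object = c("GO:root", "GO:a",
                 "GO:root", "GO:a", "GO:b",
                 "UniProtKB:P4", "UniProtKB:P5", "MI:0407",
                 "NCBITaxon:9606")))
}

test_that("term selectors match directly and through descendants", {
  g <- queryFixture()
  tpl <- queryTemplate("t", termSelector("participates_in", "GO:root"))
  hits <- evaluateTemplate(tpl, g)
  # brute-force scan oracle over all statements
  desc <- c("GO:root", "GO:a", "GO:b")
  st <- kgStatements(g)
  expected <- sort(unique(st$subject[st$predicate == "participates_in" &
                                       st$object %in% desc]))
  expect_identical(hits$protein, expected)

  exact <- evaluateTemplate(
    queryTemplate("t", termSelector("participates_in", "GO:root",
                                    useDescendants = FALSE)), g)
  expect_identical(exact$protein, "UniProtKB:P1")

  empty <- evaluateTemplate(queryTemplate("empty"), g)
  expect_equal(nrow(empty), 0L)
  expect_error(
    evaluateTemplate(queryTemplate("x", termSelector("participates_in",
                                                     "GO:missing")), g),
    "GO:missing")
})

test_that("interaction selectors respect partner, type and self-exclusion", {
  g <- queryFixture()
  both <- evaluateTemplate(
    queryTemplate("i", interactionSelector("UniProtKB:P4")), g)
  expect_identical(both$protein, "UniProtKB:P5")
  typed <- evaluateTemplate(
    queryTemplate("i", interactionSelector("UniProtKB:P4", "MI:0407")), g)
  expect_identical(typed$protein, "UniProtKB:P5")
  partnerFree <- evaluateTemplate(
    queryTemplate("i", interactionSelector(interactionType = "MI:0407")),
    g)
  expect_setequal(partnerFree$protein, c("UniProtKB:P4", "UniProtKB:P5"))
})

test_that("boolean combinators and the taxon filter compose", {
  g <- queryFixture()
  conj <- evaluateTemplate(queryTemplate("c", qAnd(
    termSelector("participates_in", "GO:root"),
    termSelector("participates_in", "GO:a"))), g)
  expect_setequal(conj$protein, c("UniProtKB:P2", "UniProtKB:P3"))
  disj <- evaluateTemplate(queryTemplate("d", qOr(
    termSelector("participates_in", "GO:b"),
    interactionSelector("UniProtKB:P4"))), g)
  expect_setequal(disj$protein, c("UniProtKB:P3", "UniProtKB:P5"))
  taxed <- evaluateTemplate(queryTemplate("t",
    termSelector("participates_in", "GO:root"),
    taxon = "NCBITaxon:9606"), g)
  expect_identical(taxed$protein, "UniProtKB:P1")
  # matched clause labels are reported
  expect_true(all(nzchar(disj$clauses)))
})

test_that("built-in templates have the documented clause structure", {
  tpls <- builtinTemplates()
  expect_named(tpls, paste0("Q", 1:5))
  q1 <- tpls$Q1$expression
  expect_equal(q1$kind, "or")
  kinds <- vapply(q1$children, function(ch) {
    if (inherits(ch, "QuerySelector")) ch$kind else ch$kind
  }, character(1))
  expect_equal(sort(kinds), sort(c("term", "term", "interaction", "and")))
  q4 <- tpls$Q4$expression
  expect_equal(q4$kind, "and")
  expect_equal(builtinTemplates(q4Mode = "union")$Q4$expression$kind, "or")
  expect_error(builtinTemplates(c(creb1 = NA_character_)), "creb1")
  expect_error(builtinTemplates(c(bogus_role = "GO:1")), "bogus_role")
})

test_that("Q4 excludes proteins lacking a degradation clause; Q5 requires the interaction", {
  kb <- generateKB(synthConfig(seed = 13, plantingMode = "Q4",
                               nPlantedRegulators = 4))
  g <- kb$graph
  # a protein with only the central term must not match
  g <- addTerms(g, "UniProtKB:ONLYC")
  g <- addStatements(g, "UniProtKB:ONLYC", "participates_in", "GO:0032088")
  cl <- computeClosure(g)$graph
  hits <- evaluateTemplate(builtinTemplates()$Q4, cl)$protein
  expect_false("UniProtKB:ONLYC" %in% hits)
  expect_setequal(hits, kb$ledger$protein)

  kb5 <- generateKB(synthConfig(seed = 13, plantingMode = "Q5",
                                nPlantedRegulators = 3))
  g5 <- kb5$graph
  g5 <- addTerms(g5, "UniProtKB:NOINT")
  g5 <- addStatements(g5, rep("UniProtKB:NOINT", 2), "participates_in",
                      c("GO:0043433", "GO:0051091"))
  cl5 <- computeClosure(g5)$graph
  hits5 <- evaluateTemplate(builtinTemplates()$Q5, cl5)$protein
  expect_false("UniProtKB:NOINT" %in% hits5)
})

test_that("filterDbtf is exact set intersection", {
  expect_length(filterDbtf(c("a", "b"), character()), 0L)
  expect_setequal(filterDbtf(c("a", "b"), c("a", "b", "c")), c("a", "b"))
  set.seed(3)
  for (i in 1:5) {
    cand <- sample(letters, 10)
    cat2 <- sample(letters, 12)
    expect_setequal(filterDbtf(cand, cat2),
                    unique(cand[cand %in% cat2]))
  }
})

test_that("sharedTargets joins regulator sets through common targets", {
  edges <- data.frame(
    regulator = c("N1", "N2", "C1", "C2"),
    target_gene = c("G1", "G2", "G3", "G4"),
    mode = "activator", source_db = "TFactS", stringsAsFactors = FALSE)
  expect_equal(nrow(sharedTargets(c("N1", "N2"), c("C1", "C2"), edges)),
               0L)

  # brute-force double loop on a random bipartite fixture
  set.seed(11)
  novel <- paste0("N", 1:4); core <- paste0("C", 1:3)
  genes <- paste0("G", 1:6)
  edges <- data.frame(
    regulator = sample(c(novel, core), 40, replace = TRUE),
    target_gene = sample(genes, 40, replace = TRUE),
    mode = sample(c("activator", "repressor"), 40, replace = TRUE),
    source_db = sample(c("TFactS", "PAZAR", "HTRI"), 40, replace = TRUE),
    stringsAsFactors = FALSE)
  rows <- sharedTargets(novel, core, edges)
  expected <- character()
  for (i in seq_len(nrow(edges))) {
    for (j in seq_len(nrow(edges))) {
      if (edges$regulator[i] %in% novel && edges$regulator[j] %in% core &&
          edges$target_gene[i] == edges$target_gene[j]) {
        expected <- union(expected, paste(edges$regulator[i],
                                          edges$regulator[j],
                                          edges$target_gene[i]))
      }
    }
  }
  expect_setequal(paste(rows$novel, rows$core, rows$target_gene), expected)
  # deterministic ordering and role symmetry up to column order
  expect_identical(rows, rows[order(rows$novel, rows$core,
                                    rows$target_gene), ])
  swapped <- sharedTargets(core, novel, edges)
  expect_setequal(paste(swapped$core, swapped$novel, swapped$target_gene),
                  paste(rows$novel, rows$core, rows$target_gene))
})

test_that("provenance partition classes are disjoint and match two-way evaluation", {
  kb <- generateKB(synthConfig(seed = 19, plantingMode = "Q2",
                               nPlantedRegulators = 6, pInferredOnly = 0.5))
  cl <- computeClosure(kb$graph)
  tpl <- builtinTemplates()$Q2
  part <- provenancePartition(tpl, kb$graph, cl$graph)
  # oracle: evaluate on each provenance slice and set-subtract
  asserted <- evaluateTemplate(tpl, kb$graph)$protein
  closure <- evaluateTemplate(tpl, cl$graph)$protein
  expect_setequal(part$inferred_only, setdiff(closure, asserted))
  expect_setequal(c(part$asserted_only, part$both), asserted)
  expect_length(intersect(part$asserted_only, part$inferred_only), 0L)
  expect_length(intersect(part$both, part$inferred_only), 0L)
  expect_equal(sum(part$counts[c("asserted_only", "both",
                                 "inferred_only")]),
               unname(part$counts["total"]))
  # with no inferred-dependent matches the partition collapses
  inert <- knowledgeGraph("i",
    nodes = data.frame(id = c("UniProtKB:Z", "GO:0032792"),
                       category = c("protein", "ontology_class")),
    relations = defaultRelations()$relations,
    statements = data.frame(subject = "UniProtKB:Z",
                            predicate = "participates_in",
                            object = "GO:0032792"))
  clInert <- computeClosure(inert, rules = "transitivity")
  partInert <- provenancePartition(
    queryTemplate("t", termSelector("participates_in", "GO:0032792")),
    inert, clInert$graph)
  expect_equal(unname(partInert$counts["inferred_only"]), 0L)
  expect_equal(unname(partInert$counts["total"]),
               length(evaluateTemplate(queryTemplate(
                 "t", termSelector("participates_in", "GO:0032792")),
                 inert)$protein))
  extra <- addStatements(kb$graph, kgNodes(kb$graph)$id[1], "is_a",
                         kgNodes(kb$graph)$id[2])
  expect_error(provenancePartition(tpl, extra, cl$graph), "not a closure")
})
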