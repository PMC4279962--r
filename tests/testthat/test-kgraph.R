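# Graph core: CURIEs, OBO parsing/serialisation, ULO assembly, sub-domain
# extraction, merging.

test_that("CURIE dialects round-trip and normalise whitespace", {
  x <- curie(c("GO", "UniProtKB", "SSB"),
             c("0010467", "P16220", "phospho serine 133"))
  expect_identical(x, c("GO:0010467", "UniProtKB:P16220",
                        "SSB:phospho_serine_133"))
  expect_identical(curie(curieNamespace(x), curieLocal(x)), x)
  expect_identical(curieFromTriple(curieToTriple(x)), x)
  expect_error(curie("", "x"), "non-empty")
  expect_error(curie("a:b", "x"), "must not contain")
})

test_that("node categories follow the namespace convention", {
  expect_identical(
    termCategory(c("UniProtKB:P1", "KEGG:ko04120", "NCBIGene:3725",
                   "NCBITaxon:9606", "SSB:x_y", "intact:EBI-1",
                   "GO:0010467", "MI:0407", "SYN:0000001")),
    c("protein", "pathway", "gene", "taxon", "modified_residue",
      "interaction", "ontology_class", "ontology_class", "ontology_class"))
})

test_that("parseOBO handles minimal chains, empty input and typedefs", {
  g <- parseOBO(c("[Term]", "id: X:A", "name: a",
                  "[Term]", "id: X:B", "is_a: X:A",
                  "[Term]", "id: X:C", "is_a: X:B"))
  expect_equal(nrow(kgNodes(g)), 3L)
  st <- kgStatements(g)
  expect_equal(nrow(st), 2L)
  expect_true(all(st$predicate == "is_a" & st$provenance == "asserted"))

  empty <- parseOBO(character())
  expect_equal(nrow(kgNodes(empty)), 0L)
  expect_equal(nrow(kgStatements(empty)), 0L)

  g2 <- parseOBO(c("[Typedef]", "id: part_of", "is_transitive: true",
                   "[Term]", "id: X:A",
                   "[Term]", "id: X:B", "relationship: part_of X:A"))
  rl <- kgRelations(g2)
  expect_true(rl$transitive[rl$id == "part_of"])
  expect_equal(kgStatements(g2)$predicate, "part_of")
})

test_that("parseOBO matches an independent stanza/line tally on a larger fixture", {
  set.seed(7)
  lines <- character()
  ids <- sprintf("X:%04d", 1:12)
  for (i in seq_along(ids)) {
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
               paste0("name: term ", i))
    if (i > 1) {
      for (p in sample(ids[seq_len(i - 1)], min(i - 1L, sample(1:2, 1)))) {
        tag <- sample(c("is_a: ", "relationship: part_of "), 1)
        lines <- c(lines, paste0(tag, p))
      }
    }
  }
  lines <- c("[Typedef]", "id: part_of", "is_transitive: true", lines)
  # independent oracle: count stanzas and edge lines directly
  expectNodes <- sum(lines == "[Term]")
  expectEdges <- sum(grepl("^(is_a|relationship):", lines))
  g <- parseOBO(lines)
  expect_equal(nrow(kgNodes(g)), expectNodes)
  expect_equal(nrow(kgStatements(g)), expectEdges)
})

test_that("parseOBO errors name the defect and warns on unknown tags", {
  expect_error(parseOBO(c("[Term]", "name: no id here")), "line 1")
  expect_error(
    parseOBO(c("[Term]", "id: X:A",
               "[Term]", "id: X:B", "relationship: undeclared_rel X:A")),
    "undeclared_rel")
  expect_warning(parseOBO(c("[Term]", "id: X:A", "def: something")),
                 "ignored OBO tags")
})

test_that("OBO serialisation round-trips nodes and asserted statements", {
  g <- parseOBO(c("[Typedef]", "id: part_of", "is_transitive: true",
                  "[Term]", "id: X:A", "name: alpha",
                  "[Term]", "id: X:B", "name: beta", "is_a: X:A",
                  "relationship: part_of X:A"))
  back <- parseOBO(serializeOBO(g), name = kgName(g))
  expect_identical(kgNodes(back)[order(kgNodes(back)$id), ],
                   kgNodes(g)[order(kgNodes(g)$id), ])
  expect_setequal(statementSet(assertedStatements(back)),
                  statementSet(assertedStatements(g)))
  # deterministic output
  expect_identical(serializeOBO(g), serializeOBO(g))
})

test_that("assembleULO builds a single-rooted hierarchy with a Biological Process anchor", {
  ulo <- assembleULO()
  nd <- kgNodes(ulo)
  expect_gte(nrow(nd), 14L)
  expect_lte(nrow(nd), 17L)
  expect_true("Biological Process" %in% nd$label)
  # every non-root reaches the root via is_a
  st <- kgStatements(ulo)
  root <- setdiff(nd$id, st$subject)
  expect_length(root, 1L)
  for (id in setdiff(nd$id, root)) {
    anc <- termDescendants(ulo, root)  # descendants of root = all reachable
    expect_true(id %in% anc)
  }

  single <- assembleULO(data.frame(id = "U:1", label = "only",
                                   parent = NA))
  expect_equal(nrow(kgNodes(single)), 1L)
  expect_equal(nrow(kgStatements(single)), 0L)

  expect_error(assembleULO(data.frame(id = c("A", "B"),
                                      label = c("a", "b"),
                                      parent = c("B", "A"))),
               "root")
  expect_error(assembleULO(data.frame(id = c("R", "A", "B"),
                                      label = c("r", "a", "b"),
                                      parent = c(NA, "B", "A"))),
               "cycle")
  expect_error(assembleULO(data.frame(id = c("R1", "R2"),
                                      label = c("r1", "r2"),
                                      parent = c(NA, NA))),
               "exactly one root")
})

test_that("extractSubdomain equals brute-force reverse reachability", {
  # 10-node toy DAG with is_a and part_of edges
  set.seed(42)
  nodes <- sprintf("D:%02d", 1:10)
  edges <- NULL
  for (i in 2:10) {
    p <- sample(seq_len(i - 1), 1)
    edges <- rbind(edges, data.frame(
      subject = nodes[i],
      predicate = sample(c("is_a", "part_of"), 1),
      object = nodes[p], stringsAsFactors = FALSE))
  }
  g <- knowledgeGraph("dag", nodes = data.frame(id = nodes),
                      relations = data.frame(
                        id = c("is_a", "part_of"),
                        transitive = TRUE),
                      statements = edges)
  # brute-force BFS oracle over reversed edges
  bfs <- function(root) {
    seen <- root
    frontier <- root
    while (length(frontier)) {
      nxt <- edges$subject[edges$object %in% frontier]
      frontier <- setdiff(nxt, seen)
      seen <- union(seen, frontier)
    }
    seen
  }
  for (root in nodes) {
    sub <- extractSubdomain(g, root)
    expect_setequal(kgNodes(sub)$id, bfs(root))
  }
  # singleton: a leaf has no descendants
  leaves <- setdiff(nodes, edges$object)
  sub <- extractSubdomain(g, leaves[1])
  expect_identical(kgNodes(sub)$id, leaves[1])
  expect_error(extractSubdomain(g, "D:99"), "D:99")
})

test_that("nested roots yield nested sub-domain statement sets", {
  # r1 <- r2 <- r3 chain with side branches, emulating nested GO sub-domains
  g <- parseOBO(c(
    "[Term]", "id: S:r1",
    "[Term]", "id: S:r2", "is_a: S:r1",
    "[Term]", "id: S:r3", "is_a: S:r2",
    "[Term]", "id: S:a", "is_a: S:r3",
    "[Term]", "id: S:b", "is_a: S:r2",
    "[Term]", "id: S:c", "is_a: S:r1",
    "[Term]", "id: S:d", "is_a: S:a"))
  s1 <- statementSet(kgStatements(extractSubdomain(g, "S:r1")))
  s2 <- statementSet(kgStatements(extractSubdomain(g, "S:r2")))
  s3 <- statementSet(kgStatements(extractSubdomain(g, "S:r3")))
  expect_true(all(s3 %in% s2))
  expect_true(all(s2 %in% s1))
  expect_gt(length(s1), length(s2))
})

test_that("linkToULO adds exactly one is_a statement and is idempotent", {
  ulo <- assembleULO()
  frag <- knowledgeGraph("frag", nodes = data.frame(id = "F:1"),
                         relations = data.frame(id = "is_a",
                                                transitive = TRUE))
  merged <- linkToULO(ulo, frag, "F:1", "ULO:0000010")
  expect_equal(nrow(kgNodes(merged)), nrow(kgNodes(ulo)) + 1L)
  expect_equal(nrow(kgStatements(merged)), nrow(kgStatements(ulo)) + 1L)
  again <- linkToULO(merged, frag, "F:1", "ULO:0000010")
  expect_equal(nrow(kgStatements(again)), nrow(kgStatements(merged)))
  expect_error(linkToULO(ulo, frag, "F:1", "ULO:9999999"), "anchor")
})

test_that("mergeGraphs is an idempotent, commutative, associative set union", {
  g1 <- randomKGraph(1, nNodes = 12, nStatements = 25)
  g2 <- randomKGraph(2, nNodes = 12, nStatements = 25)
  g3 <- randomKGraph(3, nNodes = 12, nStatements = 25)

  expect_setequal(statementSet(kgStatements(mergeGraphs(list(g1, g1)))),
                  statementSet(kgStatements(g1)))

  # disjoint graphs: counts add
  h1 <- knowledgeGraph("h1", nodes = data.frame(id = sprintf("A:%d", 1:5)),
                       relations = data.frame(id = "is_a",
                                              transitive = TRUE),
                       statements = data.frame(
                         subject = sprintf("A:%d", 2:5), predicate = "is_a",
                         object = sprintf("A:%d", 1:4)))
  h2 <- knowledgeGraph("h2", nodes = data.frame(id = sprintf("B:%d", 1:5)),
                       relations = data.frame(id = "is_a",
                                              transitive = TRUE),
                       statements = data.frame(
                         subject = sprintf("B:%d", 2:5), predicate = "is_a",
                         object = sprintf("B:%d", 1:4)))
  m <- mergeGraphs(list(h1, h2))
  expect_equal(nrow(kgNodes(m)), 10L)
  expect_equal(nrow(kgStatements(m)), 8L)

  # overlap: statement count equals independent set-union size
  u12 <- union(statementSet(kgStatements(g1)),
               statementSet(kgStatements(g2)))
  expect_setequal(statementSet(kgStatements(mergeGraphs(list(g1, g2)))),
                  u12)
  ab <- mergeGraphs(list(mergeGraphs(list(g1, g2)), g3))
  bc <- mergeGraphs(list(g1, mergeGraphs(list(g2, g3))))
  ba <- mergeGraphs(list(g2, g1, g3))
  expect_setequal(statementSet(kgStatements(ab)),
                  statementSet(kgStatements(bc)))
  expect_setequal(statementSet(kgStatements(ab)),
                  statementSet(kgStatements(ba)))

  # conflicting relation metadata is an error
  c1 <- knowledgeGraph("c1", relations = data.frame(id = "part_of",
                                                    transitive = TRUE))
  c2 <- knowledgeGraph("c2", relations = data.frame(id = "part_of",
                                                    transitive = FALSE))
  expect_error(mergeGraphs(list(c1, c2)), "part_of")
})

test_that("merge keeps asserted provenance over inferred on collision", {
  nodes <- data.frame(id = c("X:a", "X:b"))
  rel <- data.frame(id = "is_a", transitive = TRUE)
  gA <- knowledgeGraph("a", nodes = nodes, relations = rel,
                       statements = data.frame(subject = "X:a",
                                               predicate = "is_a",
                                               object = "X:b",
                                               provenance = "inferred"))
  gB <- knowledgeGraph("b", nodes = nodes, relations = rel,
                       statements = data.frame(subject = "X:a",
                                               predicate = "is_a",
                                               object = "X:b",
                                               provenance = "asserted"))
  m <- mergeGraphs(list(gA, gB))
  expect_equal(nrow(kgStatements(m)), 1L)
  expect_equal(kgStatements(m)$provenance, "asserted")
})

test_that("N-Triples export is sorted, filtered by provenance, and uses the triple dialect", {
  g <- chainGraph(3)
  cl <- computeClosure(g)$graph
  allLines <- writeNTriples(cl)
  expect_identical(allLines, sort(allLines))
  expect_equal(length(allLines), nrow(kgStatements(cl)))
  aLines <- writeNTriples(cl, provenance = "asserted")
  iLines <- writeNTriples(cl, provenance = "inferred")
  expect_equal(length(aLines) + length(iLines), length(allLines))
  expect_true(all(grepl("C_0", allLines)))  # underscore dialect
})
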