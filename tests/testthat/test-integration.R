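# Core-protein selection, association extension and graph population.

seedWith <- function(terms) {
  knowledgeGraph("seed", nodes = data.frame(id = terms),
                 relations = data.frame(id = "is_a", transitive = TRUE))
}

test_that("core proteins require a P-aspect annotation to a seed term", {
  ann <- data.frame(
    protein = c("UniProtKB:P1", "UniProtKB:P2", "UniProtKB:P3",
                "UniProtKB:P2", "UniProtKB:P4", "UniProtKB:P4"),
    go_term = c("GO:1", "GO:2", "GO:3", "GO:4", "GO:5", "GO:1"),
    aspect = c("P", "P", "F", "P", "P", "C"),
    stringsAsFactors = FALSE)
  seed <- seedWith(c("GO:1", "GO:2"))
  # nested-loop oracle
  expected <- character()
  for (i in seq_len(nrow(ann))) {
    if (ann$aspect[i] == "P" && ann$go_term[i] %in% c("GO:1", "GO:2")) {
      expected <- union(expected, ann$protein[i])
    }
  }
  expect_setequal(selectCoreProteins(ann, seed), expected)

  noP <- ann[ann$aspect != "P", , drop = FALSE]
  expect_length(selectCoreProteins(noP, seed), 0L)

  # monotonicity under seed widening
  narrow <- selectCoreProteins(ann, seedWith("GO:1"))
  wide <- selectCoreProteins(ann, seedWith(c("GO:1", "GO:2", "GO:4")))
  expect_true(all(narrow %in% wide))
})

test_that("association extension is a single-round neighbourhood union", {
  ia <- data.frame(participant_a = "UniProtKB:A",
                   participant_b = "UniProtKB:B",
                   stringsAsFactors = FALSE)
  ia <- rbind(ia, data.frame(participant_a = "UniProtKB:B",
                             participant_b = "UniProtKB:C"))
  res <- extendByAssociation("UniProtKB:A", interactions = ia)
  expect_setequal(res, c("UniProtKB:A", "UniProtKB:B"))  # no C: one round

  expect_length(extendByAssociation(character(), interactions = ia), 0L)

  # randomized fixture vs brute-force one-round union
  set.seed(5)
  prot <- sprintf("UniProtKB:R%02d", 1:30)
  ia <- data.frame(participant_a = sample(prot, 25, replace = TRUE),
                   participant_b = sample(prot, 25, replace = TRUE),
                   stringsAsFactors = FALSE)
  pw <- data.frame(protein = sample(prot, 20, replace = TRUE),
                   pathway = sample(sprintf("KEGG:p%d", 1:4), 20,
                                    replace = TRUE),
                   stringsAsFactors = FALSE)
  orth <- data.frame(protein_a = sample(prot, 8),
                     protein_b = sample(prot, 8), stringsAsFactors = FALSE)
  core <- sample(prot, 5)
  expected <- core
  for (p in prot) {
    linked <- FALSE
    for (i in seq_len(nrow(ia))) {
      if ((ia$participant_a[i] == p && ia$participant_b[i] %in% core) ||
          (ia$participant_b[i] == p && ia$participant_a[i] %in% core)) {
        linked <- TRUE
      }
    }
    corePws <- pw$pathway[pw$protein %in% core]
    if (p %in% pw$protein[pw$pathway %in% corePws]) linked <- TRUE
    for (i in seq_len(nrow(orth))) {
      if ((orth$protein_a[i] == p && orth$protein_b[i] %in% core) ||
          (orth$protein_b[i] == p && orth$protein_a[i] %in% core)) {
        linked <- TRUE
      }
    }
    if (linked) expected <- union(expected, p)
  }
  expect_setequal(extendByAssociation(core, ia, pw, orth), expected)
})

test_that("populateGraph reifies interactions and tallies per predicate", {
  seed <- seedWith(c("GO:1", "GO:2", "MI:0914"))
  ann <- data.frame(protein = "UniProtKB:P1", go_term = "GO:1",
                    aspect = "P", stringsAsFactors = FALSE)
  g <- populateGraph(seed, "UniProtKB:P1", annotations = ann)
  st <- kgStatements(g)
  expect_equal(sum(st$predicate == "participates_in"), 1L)

  ia <- data.frame(interaction_id = "intact:EBI-1",
                   participant_a = "UniProtKB:P1",
                   participant_b = "UniProtKB:P2",
                   interaction_type = "MI:0914", stringsAsFactors = FALSE)
  g2 <- populateGraph(seed, c("UniProtKB:P1", "UniProtKB:P2"),
                      interactions = ia)
  st2 <- kgStatements(g2)
  around <- st2[st2$subject == "intact:EBI-1", ]
  expect_equal(nrow(around), 3L)
  expect_equal(sum(around$predicate == "has_participant"), 2L)
  expect_equal(sum(around$predicate == "has_interaction_type"), 1L)
  expect_equal(kgNodes(g2)$category[kgNodes(g2)$id == "intact:EBI-1"],
               "interaction")
})

test_that("populateGraph statement counts equal independent per-record tallies", {
  kb <- generateKB(synthConfig(seed = 8, nProteins = 30,
                               nPlantedRegulators = 0))
  rec <- kb$records
  st <- kgStatements(kb$graph)
  # annotations are unique per (protein, term, aspect) after dedup
  uniqAnn <- unique(rec$annotations[c("protein", "go_term", "aspect")])
  tal <- table(factor(uniqAnn$aspect, c("P", "F", "C")))
  expect_equal(sum(st$predicate == "participates_in"),
               unname(tal[["P"]]))
  expect_equal(sum(st$predicate == "has_function"), unname(tal[["F"]]))
  expect_equal(sum(st$predicate == "located_in"), unname(tal[["C"]]))
  expect_equal(sum(st$predicate == "has_interaction_type"),
               nrow(rec$interactions))
  expect_equal(sum(st$predicate == "has_participant"),
               nrow(unique(rbind(
                 rec$interactions[c("interaction_id", "participant_a")],
                 stats::setNames(
                   rec$interactions[c("interaction_id", "participant_b")],
                   c("interaction_id", "participant_a"))))))
  expect_equal(sum(st$predicate == "member_of_pathway"),
               nrow(unique(rec$pathways)))
  expect_equal(sum(st$predicate == "encoded_by"),
               sum(nzchar(rec$infos$gene)))
  expect_equal(sum(st$predicate %in% c("activates", "represses",
                                       "regulates")),
               nrow(unique(rec$edges[c("regulator", "target_gene",
                                       "mode")])))
})

test_that("populated graphs satisfy the structural invariants", {
  kb <- generateKB(synthConfig(seed = 21))
  nd <- kgNodes(kb$graph)
  st <- kgStatements(kb$graph)
  # closed under reference
  expect_true(all(c(st$subject, st$object) %in% nd$id))
  # gene nodes never outnumber protein nodes
  expect_lte(sum(nd$category == "gene"), sum(nd$category == "protein"))
  # unknown annotation terms are an error unless skipped
  seed <- seedWith("GO:1")
  badAnn <- data.frame(protein = "UniProtKB:P1", go_term = "GO:404",
                       aspect = "P", stringsAsFactors = FALSE)
  expect_error(populateGraph(seed, "UniProtKB:P1", annotations = badAnn),
               "GO:404")
  ok <- populateGraph(seed, "UniProtKB:P1", annotations = badAnn,
                      skipUnknownTerms = TRUE)
  expect_equal(sum(kgStatements(ok)$predicate == "participates_in"), 0L)
})
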