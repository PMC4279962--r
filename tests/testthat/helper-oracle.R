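# Independent oracles used across the suite. The closure oracle is a naive
# fixpoint over dense logical adjacency matrices (one per relation), re-scanning
# every rule each round until nothing changes -- a deliberately different
# route from the package's incremental data.frame joins.

statementSet <- function(st) {
  sort(paste(st$subject, st$predicate, st$object, sep = " | "))
}

naiveClosureOracle <- function(graph, priorityObj = TRUE,
                               prioritySubj = TRUE) {
  nodes <- kgNodes(graph)$id
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  rl <- kgRelations(graph)
  sr <- kgSuperRelations(graph)
  cp <- kgCompositions(graph)
  st <- kgStatements(graph)

  mats <- list()
  matFor <- function(r) {
    if (is.null(mats[[r]])) mats[[r]] <<- matrix(FALSE, n, n)
    mats[[r]]
  }
  for (r in unique(st$predicate)) {
    m <- matrix(FALSE, n, n)
    rows <- st[st$predicate == r, , drop = FALSE]
    m[cbind(idx[rows$subject], idx[rows$object])] <- TRUE
    mats[[r]] <- m
  }
  boolmul <- function(a, b) (a %*% b) > 0

  repeat {
    changed <- FALSE
    upd <- function(r, new) {
      cur <- matFor(r)
      merged <- cur | new
      if (any(merged != cur)) {
        mats[[r]] <<- merged
        changed <<- TRUE
      }
    }
    for (r in rl$id[rl$reflexive]) {
      m <- matFor(r)
      touched <- which(rowSums(m) > 0 | colSums(m) > 0)
      if (length(touched)) {
        d <- matrix(FALSE, n, n)
        d[cbind(touched, touched)] <- TRUE
        upd(r, d)
      }
    }
    if (nrow(sr)) {
      for (i in seq_len(nrow(sr))) {
        upd(sr$superrelation[i], matFor(sr$relation[i]))
      }
    }
    isa <- matFor("is_a")
    for (r in rl$id[rl$priority_over_subsumption]) {
      m <- matFor(r)
      if (priorityObj) upd(r, boolmul(m, isa))
      if (prioritySubj) upd(r, boolmul(isa, m))
    }
    for (r in rl$id[rl$transitive]) {
      m <- matFor(r)
      upd(r, boolmul(m, m))
    }
    if (nrow(cp)) {
      for (i in seq_len(nrow(cp))) {
        upd(cp$produces[i],
            boolmul(matFor(cp$relation[i]), matFor(cp$second[i])))
      }
    }
    if (!changed) break
  }

  out <- NULL
  for (r in names(mats)) {
    w <- which(mats[[r]], arr.ind = TRUE)
    if (nrow(w)) {
      out <- rbind(out, data.frame(subject = nodes[w[, 1]], predicate = r,
                                   object = nodes[w[, 2]],
                                   stringsAsFactors = FALSE))
    }
  }
  statementSet(out)
}

# Random graphs with rule-bearing relation metadata: an is_a hierarchy plus
# data relations exercising all five rules.
randomKGraph <- function(seed, nNodes = 30L, nStatements = 90L) {
  set.seed(seed)
  nodes <- sprintf("N:%03d", seq_len(nNodes))
  relations <- data.frame(
    id = c("is_a", "part_of", "annotated_to", "binds", "directly_binds",
           "connected_to", "linked_to"),
    transitive = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    reflexive = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    priority_over_subsumption = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                                  FALSE),
    stringsAsFactors = FALSE)
  superRelations <- data.frame(relation = "directly_binds",
                               superrelation = "binds",
                               stringsAsFactors = FALSE)
  compositions <- data.frame(relation = "annotated_to", second = "part_of",
                             produces = "annotated_to",
                             stringsAsFactors = FALSE)
  # is_a edges only downward in index order: guarantees acyclicity so the
  # closure stays small and comparable
  isaN <- min(nStatements %/% 3L, nNodes * 2L)
  subj <- sample(2:nNodes, isaN, replace = TRUE)
  obj <- vapply(subj, function(s) sample.int(s - 1L, 1L), integer(1))
  st <- data.frame(subject = nodes[subj], predicate = "is_a",
                   object = nodes[obj], stringsAsFactors = FALSE)
  others <- c("part_of", "annotated_to", "binds", "directly_binds",
              "connected_to", "linked_to")
  rest <- nStatements - isaN
  if (rest > 0L) {
    subj <- sample(2:nNodes, rest, replace = TRUE)
    obj <- vapply(subj, function(s) sample.int(s - 1L, 1L), integer(1))
    st <- rbind(st, data.frame(
      subject = nodes[subj],
      predicate = sample(others, rest, replace = TRUE),
      object = nodes[obj], stringsAsFactors = FALSE))
  }
  st <- unique(st)
  knowledgeGraph(paste0("rand-", seed),
                 nodes = data.frame(id = nodes),
                 relations = relations, superRelations = superRelations,
                 compositions = compositions, statements = st)
}

# Linear chain a1 -r-> a2 -r-> ... of L edges.
chainGraph <- function(L, relation = "r", transitive = TRUE) {
  nodes <- sprintf("C:%02d", seq_len(L + 1L))
  knowledgeGraph("chain",
    nodes = data.frame(id = nodes),
    relations = data.frame(id = relation, transitive = transitive),
    statements = data.frame(subject = nodes[-(L + 1L)],
                            predicate = relation,
                            object = nodes[-1L]))
}
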