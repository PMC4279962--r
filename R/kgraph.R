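#' Construct a KnowledgeGraph
#'
#' Low-level constructor. Most users build graphs through [parseOBO()],
#' [assembleULO()], [populateGraph()] or [generateKB()]; this function
#' normalises the component tables, fills in node categories from the CURIE
#' namespace and enforces the class invariants (reference closure, unique
#' `(subject, predicate, object)` triples with asserted provenance winning on
#' collision).
#'
#' @param name Graph name.
#' @param nodes `data.frame` with columns `id` and optionally `label`,
#'   `category` (missing categories are derived via [termCategory()]).
#' @param relations `data.frame` with column `id` and optionally `name`,
#'   `transitive`, `reflexive`, `priority_over_subsumption`.
#' @param superRelations `data.frame` with columns `relation`,
#'   `superrelation`.
#' @param compositions `data.frame` with columns `relation`, `second`,
#'   `produces`.
#' @param statements `data.frame` with columns `subject`, `predicate`,
#'   `object` and optionally `provenance` (default `"asserted"`) and `source`.
#' @return A [KnowledgeGraph-class].
#' @examples
#' g <- knowledgeGraph(
#'   "toy",
#'   nodes = data.frame(id = c("GO:1", "GO:2")),
#'   relations = data.frame(id = "is_a", transitive = TRUE),
#'   statements = data.frame(subject = "GO:2", predicate = "is_a",
#'                           object = "GO:1")
#' )
#' @export
knowledgeGraph <- function(name = "kg",
                           nodes = NULL, relations = NULL,
                           superRelations = NULL, compositions = NULL,
                           statements = NULL) {
  new("KnowledgeGraph",
      name = name,
      nodes = normaliseNodes(nodes),
      relations = normaliseRelations(relations),
      superRelations = normaliseSuperRelations(superRelations),
      compositions = normaliseCompositions(compositions),
      statements = dedupStatements(normaliseStatements(statements)))
}

normaliseNodes <- function(nodes) {
  if (is.null(nodes) || !nrow(as.data.frame(nodes))) return(emptyNodeTable())
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(nodes))
  if (is.null(nodes$label)) nodes$label <- nodes$id
  nodes$label[is.na(nodes$label)] <- nodes$id[is.na(nodes$label)]
  if (is.null(nodes$category)) nodes$category <- termCategory(nodes$id)
  nodes <- nodes[c("id", "label", "category")]
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes
}

normaliseRelations <- function(relations) {
  if (is.null(relations) || !nrow(as.data.frame(relations))) {
    return(emptyRelationTable())
  }
  rl <- as.data.frame(relations, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(rl))
  if (is.null(rl$name)) rl$name <- rl$id
  for (flag in c("transitive", "reflexive", "priority_over_subsumption")) {
    if (is.null(rl[[flag]])) rl[[flag]] <- FALSE
    rl[[flag]][is.na(rl[[flag]])] <- FALSE
    rl[[flag]] <- as.logical(rl[[flag]])
  }
  rl <- rl[c("id", "name", "transitive", "reflexive",
             "priority_over_subsumption")]
  rl <- rl[!duplicated(rl$id), , drop = FALSE]
  rownames(rl) <- NULL
  rl
}

normaliseSuperRelations <- function(sr) {
  if (is.null(sr) || !nrow(as.data.frame(sr))) {
    return(emptySuperRelationTable())
  }
  sr <- as.data.frame(sr, stringsAsFactors = FALSE)
  stopifnot(all(c("relation", "superrelation") %in% names(sr)))
  sr <- unique(sr[c("relation", "superrelation")])
  rownames(sr) <- NULL
  sr
}

normaliseCompositions <- function(cp) {
  if (is.null(cp) || !nrow(as.data.frame(cp))) {
    return(emptyCompositionTable())
  }
  cp <- as.data.frame(cp, stringsAsFactors = FALSE)
  stopifnot(all(c("relation", "second", "produces") %in% names(cp)))
  cp <- unique(cp[c("relation", "second", "produces")])
  rownames(cp) <- NULL
  cp
}

normaliseStatements <- function(st) {
  if (is.null(st) || !nrow(as.data.frame(st))) return(emptyStatementTable())
  st <- as.data.frame(st, stringsAsFactors = FALSE)
  stopifnot(all(c("subject", "predicate", "object") %in% names(st)))
  if (is.null(st$provenance)) st$provenance <- "asserted"
  if (is.null(st$source)) st$source <- ""
  st <- st[c("subject", "predicate", "object", "provenance", "source")]
  rownames(st) <- NULL
  st
}

## Asserted-first dedup on the (s, p, o) key: order puts asserted rows ahead
## of inferred ones, duplicated() then keeps the first occurrence.
dedupStatements <- function(st) {
  if (!nrow(st)) return(st)
  st <- st[order(st$provenance != "asserted"), , drop = FALSE]
  st <- st[!duplicated(statementKey(st)), , drop = FALSE]
  rownames(st) <- NULL
  st
}

#' Add terms, relation types or statements to a graph
#'
#' Functional updates: each returns a new graph. `addTerms()` skips ids
#' already present (first declaration wins, so existing labels are kept).
#' `addStatements()` deduplicates on `(subject, predicate, object)` with
#' asserted provenance taking precedence; subjects, objects and predicates
#' must already be declared.
#'
#' @param graph A [KnowledgeGraph-class].
#' @param id,label Character vectors (recycled) of term or relation ids and
#'   labels.
#' @return The updated [KnowledgeGraph-class].
#' @export
addTerms <- function(graph, id, label = id) {
  add <- normaliseNodes(data.frame(id = id, label = label,
                                   stringsAsFactors = FALSE))
  add <- add[!add$id %in% graph@nodes$id, , drop = FALSE]
  if (nrow(add)) graph@nodes <- rbind(graph@nodes, add)
  rownames(graph@nodes) <- NULL
  validObject(graph)
  graph
}

#' @rdname addTerms
#' @param transitive,reflexive,priority_over_subsumption Logical flags for
#'   the added relation types.
#' @export
addRelationTypes <- function(graph, id, label = id, transitive = FALSE,
                             reflexive = FALSE,
                             priority_over_subsumption = FALSE) {
  add <- normaliseRelations(data.frame(
    id = id, name = label, transitive = transitive, reflexive = reflexive,
    priority_over_subsumption = priority_over_subsumption,
    stringsAsFactors = FALSE))
  add <- add[!add$id %in% graph@relations$id, , drop = FALSE]
  if (nrow(add)) graph@relations <- rbind(graph@relations, add)
  rownames(graph@relations) <- NULL
  validObject(graph)
  graph
}

#' @rdname addTerms
#' @param subject,predicate,object Character vectors (recycled) forming the
#'   statements to add.
#' @param provenance `"asserted"` or `"inferred"`.
#' @param source Free-text source tag (input file or rule name).
#' @export
addStatements <- function(graph, subject, predicate, object,
                          provenance = "asserted", source = "") {
  add <- normaliseStatements(data.frame(
    subject = subject, predicate = predicate, object = object,
    provenance = provenance, source = source, stringsAsFactors = FALSE))
  graph@statements <- dedupStatements(rbind(graph@statements, add))
  validObject(graph)
  graph
}

#' Merge knowledge graphs
#'
#' Set union of nodes, relation types and statements, deduplicated.
#' Statements present in several graphs keep asserted provenance if any copy
#' is asserted. Conflicting metadata for the same relation id (e.g. one graph
#' declaring `part_of` transitive and another not) is an error, listing the
#' offending ids. The operation is associative and commutative up to
#' statement-set equality.
#'
#' @param graphs List of [KnowledgeGraph-class] objects (a single graph is
#'   also accepted).
#' @param name Name for the merged graph.
#' @return A merged [KnowledgeGraph-class].
#' @examples
#' u <- assembleULO()
#' identical(kgStatements(mergeGraphs(list(u, u))), kgStatements(u))
#' @export
mergeGraphs <- function(graphs, name = "merged") {
  if (is(graphs, "KnowledgeGraph")) graphs <- list(graphs)
  stopifnot(length(graphs) >= 1L,
            all(vapply(graphs, is, logical(1), "KnowledgeGraph")))
  rl <- do.call(rbind, lapply(graphs, function(g) g@relations))
  rl <- unique(rl)
  if (anyDuplicated(rl$id)) {
    bad <- unique(rl$id[duplicated(rl$id)])
    stop("conflicting RelationType metadata for: ", toString(bad))
  }
  nd <- do.call(rbind, lapply(graphs, function(g) g@nodes))
  nd <- nd[!duplicated(nd$id), , drop = FALSE]
  st <- dedupStatements(do.call(rbind, lapply(graphs,
                                              function(g) g@statements)))
  sr <- unique(do.call(rbind, lapply(graphs, function(g) g@superRelations)))
  cp <- unique(do.call(rbind, lapply(graphs, function(g) g@compositions)))
  rownames(nd) <- rownames(rl) <- rownames(sr) <- rownames(cp) <- NULL
  new("KnowledgeGraph", name = name, nodes = nd, relations = rl,
      superRelations = sr, compositions = cp, statements = st)
}

#' Assemble the upper-level ontology (ULO)
#'
#' Builds the small common root structure that glues ontology fragments and
#' data-facing terms together. The default specification mirrors the usual
#' upper-level layout of protein-centric application ontologies: a single
#' root (`entity`) splitting into material entities (chemical entity,
#' protein, gene, protein complex, organism), processes (biological process,
#' pathway, molecular interaction) and informational/attribute terms. The
#' `'Biological Process'` term (`ULO:0000006`) is the anchor under which
#' ontology sub-domain fragments are linked by [linkToULO()].
#'
#' @param spec `data.frame` with columns `id`, `label`, `parent` (`NA` parent
#'   marks the root). Must be acyclic with exactly one root.
#' @return A [KnowledgeGraph-class] whose statements are asserted `is_a`
#'   links mirroring the specification.
#' @examples
#' ulo <- assembleULO()
#' subset(kgNodes(ulo), label == "Biological Process")
#' @export
assembleULO <- function(spec = uloSpec()) {
  spec <- as.data.frame(spec, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "label", "parent") %in% names(spec)))
  if (anyDuplicated(spec$id)) stop("duplicate term ids in ULO spec")
  roots <- spec$id[is.na(spec$parent) | spec$parent == ""]
  if (length(roots) != 1L) {
    stop("ULO spec must have exactly one root, found ", length(roots))
  }
  unknown <- setdiff(stats::na.omit(spec$parent), c(spec$id, ""))
  if (length(unknown)) {
    stop("ULO spec parents not declared: ", toString(unknown))
  }
  ## cycle check: repeatedly strip leaves; leftovers form a cycle
  remaining <- spec[!is.na(spec$parent) & spec$parent != "", ]
  ids <- spec$id
  repeat {
    leaves <- setdiff(ids, remaining$parent)
    drop <- remaining$id %in% leaves
    if (!any(drop)) break
    remaining <- remaining[!drop, , drop = FALSE]
    ids <- setdiff(ids, leaves)
    if (!nrow(remaining)) break
  }
  if (nrow(remaining)) {
    stop("cycle in ULO spec involving: ", toString(remaining$id))
  }
  g <- knowledgeGraph("ULO",
    nodes = data.frame(id = spec$id, label = spec$label),
    relations = data.frame(id = "is_a", transitive = TRUE))
  links <- spec[!is.na(spec$parent) & spec$parent != "", , drop = FALSE]
  if (nrow(links)) {
    g <- addStatements(g, links$id, "is_a", links$parent,
                       source = "ulo-spec")
  }
  g
}

#' @rdname assembleULO
#' @export
uloSpec <- function() {
  data.frame(
    id = paste0("ULO:", sprintf("%07d", 1:15)),
    label = c("entity", "material entity", "process", "information entity",
              "chemical entity", "protein", "gene", "protein complex",
              "organism", "Biological Process", "pathway",
              "molecular interaction", "attribute", "modified residue",
              "database record"),
    parent = c(NA, "ULO:0000001", "ULO:0000001", "ULO:0000001",
               "ULO:0000002", "ULO:0000005", "ULO:0000004", "ULO:0000002",
               "ULO:0000002", "ULO:0000003", "ULO:0000003", "ULO:0000003",
               "ULO:0000001", "ULO:0000013", "ULO:0000004"),
    stringsAsFactors = FALSE
  )
}

#' Extract an ontology sub-domain
#'
#' Returns the sub-graph rooted at `root`: the root plus every node from
#' which `root` is reachable along `edgePredicates` statements (its
#' descendants), together with *all* statements whose subject and object both
#' fall in that node set. Used to carve nested sub-domains (e.g. "gene
#' expression" ⊇ "regulation of gene expression" ⊇ "regulation of
#' transcription") out of one source ontology; nested roots yield nested
#' statement sets.
#'
#' @param graph A [KnowledgeGraph-class].
#' @param root CURIE of the sub-domain root (must exist in `graph`).
#' @param edgePredicates Relation ids followed child-to-parent; defaults to
#'   `is_a` and `part_of`.
#' @param name Name for the extracted graph.
#' @return A [KnowledgeGraph-class].
#' @export
extractSubdomain <- function(graph, root,
                             edgePredicates = c("is_a", "part_of"),
                             name = paste0(kgName(graph), "[", root, "]")) {
  if (!root %in% graph@nodes$id) {
    stop("sub-domain root not in graph: ", root)
  }
  keep <- reachableFrom(graph, root, edgePredicates, direction = "in")
  nd <- graph@nodes[graph@nodes$id %in% keep, , drop = FALSE]
  st <- graph@statements
  st <- st[st$subject %in% keep & st$object %in% keep, , drop = FALSE]
  rownames(nd) <- rownames(st) <- NULL
  new("KnowledgeGraph", name = name, nodes = nd, relations = graph@relations,
      superRelations = graph@superRelations,
      compositions = graph@compositions, statements = st)
}

## Reachability over a predicate-restricted edge set, via igraph.
## direction "in": nodes that can reach `from` (descendants when edges point
## child -> parent); "out": nodes reachable from `from` (ancestors).
reachableFrom <- function(graph, from, predicates, direction = c("in", "out")) {
  direction <- match.arg(direction)
  st <- graph@statements
  st <- st[st$predicate %in% predicates, c("subject", "object"), drop = FALSE]
  if (!nrow(st)) return(from)
  ig <- igraph::graph_from_data_frame(st, directed = TRUE,
                                      vertices = graph@nodes$id)
  found <- lapply(from, function(f) {
    names(igraph::subcomponent(ig, f, mode = direction))
  })
  unique(c(from, unlist(found)))
}

#' Descendants of a term
#'
#' All nodes from which `term` is reachable via the given predicates
#' (`term` itself included). This is the descendant set used by
#' closure-aware query selectors.
#'
#' @inheritParams extractSubdomain
#' @param term CURIE of the term.
#' @param predicates Relation ids to traverse (default `is_a`).
#' @return Character vector of CURIEs.
#' @export
termDescendants <- function(graph, term, predicates = "is_a") {
  if (!all(term %in% graph@nodes$id)) {
    stop("term not in graph: ", toString(setdiff(term, graph@nodes$id)))
  }
  reachableFrom(graph, term, predicates, direction = "in")
}

#' Link an ontology fragment under a ULO anchor
#'
#' Merges `fragment` into `ulo` and adds exactly one asserted `is_a`
#' statement from the fragment root to the anchor term (e.g. linking a GO
#' sub-domain root as a subclass of 'Biological Process'). Re-linking an
#' already linked fragment is a no-op thanks to statement deduplication.
#'
#' @param ulo The upper-level ontology graph (must contain `anchor`).
#' @param fragment The fragment graph (must contain `fragmentRoot`).
#' @param fragmentRoot CURIE of the fragment root.
#' @param anchor CURIE of the ULO anchor term.
#' @param name Name for the merged graph.
#' @return A merged [KnowledgeGraph-class].
#' @export
linkToULO <- function(ulo, fragment, fragmentRoot, anchor,
                      name = kgName(ulo)) {
  if (!anchor %in% kgNodes(ulo)$id) stop("anchor not in ULO: ", anchor)
  if (!fragmentRoot %in% kgNodes(fragment)$id) {
    stop("fragment root not in fragment: ", fragmentRoot)
  }
  g <- mergeGraphs(list(ulo, fragment), name = name)
  addStatements(g, fragmentRoot, "is_a", anchor, source = "ulo-link")
}
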