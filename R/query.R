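#' Query selectors
#'
#' The atoms of the query algebra. A *term selector* matches proteins
#' linked by `predicate` to `term` — or, when `useDescendants` is `TRUE`
#' (the default, mirroring queries against the closed graph), to any
#' `is_a` descendant of `term`. An *interaction selector* matches proteins
#' co-participating in a reified interaction node with `partner`, of the
#' given interaction type (either may be omitted, not both; type matching
#' extends to type descendants when `useDescendants`).
#'
#' Selectors are combined with [qAnd()] / [qOr()] into a boolean expression
#' tree and wrapped by [queryTemplate()].
#'
#' @param predicate Relation id (e.g. `"participates_in"`).
#' @param term,partner,interactionType CURIEs.
#' @param useDescendants Extend matching to `is_a` descendants.
#' @param label Clause label reported in results (defaults to a readable
#'   rendering).
#' @return A selector object (S3).
#' @export
termSelector <- function(predicate, term, useDescendants = TRUE,
                         label = paste0(predicate, "=", term)) {
  structure(list(kind = "term", predicate = predicate, term = term,
                 useDescendants = useDescendants, label = label),
            class = c("TermSelector", "QuerySelector"))
}

#' @rdname termSelector
#' @export
interactionSelector <- function(partner = NULL, interactionType = NULL,
                                useDescendants = TRUE,
                                label = paste0("interacts(",
                                               paste(c(partner,
                                                       interactionType),
                                                     collapse = ","), ")")) {
  if (is.null(partner) && is.null(interactionType)) {
    stop("interactionSelector needs a partner or an interaction type")
  }
  structure(list(kind = "interaction", partner = partner,
                 interactionType = interactionType,
                 useDescendants = useDescendants, label = label),
            class = c("InteractionSelector", "QuerySelector"))
}

#' @rdname termSelector
#' @param ... Child selectors or sub-expressions.
#' @export
qAnd <- function(...) {
  structure(list(kind = "and", children = list(...)),
            class = "QueryExpression")
}

#' @rdname termSelector
#' @export
qOr <- function(...) {
  structure(list(kind = "or", children = list(...)),
            class = "QueryExpression")
}

#' Build a query template
#'
#' A named boolean expression over selectors, optionally restricted to one
#' taxon (proteins must carry a matching `in_taxon` statement). Evaluation
#' is pure and deterministic.
#'
#' @param name Template name (`Q1`..`Q6` for the built-ins, or any string).
#' @param expression A selector or [qAnd()]/[qOr()] expression tree; `NULL`
#'   gives an empty template matching nothing.
#' @param taxon Optional taxon CURIE filter.
#' @return A `QueryTemplate` (S3).
#' @seealso [builtinTemplates()], [evaluateTemplate()]
#' @export
queryTemplate <- function(name, expression = NULL, taxon = NULL) {
  structure(list(name = name, expression = expression, taxon = taxon),
            class = "QueryTemplate")
}

#' @export
print.QueryTemplate <- function(x, ...) {
  cat("QueryTemplate", x$name, "\n")
  render <- function(e, indent) {
    pad <- strrep("  ", indent)
    if (is.null(e)) { cat(pad, "(empty)\n", sep = ""); return(invisible()) }
    if (inherits(e, "QuerySelector")) {
      cat(pad, e$label, "\n", sep = "")
    } else {
      cat(pad, toupper(e$kind), "\n", sep = "")
      for (ch in e$children) render(ch, indent + 1L)
    }
  }
  render(x$expression, 1L)
  if (!is.null(x$taxon)) cat("  taxon:", x$taxon, "\n")
  invisible(x)
}

## Leaf evaluation: set of matching protein CURIEs.
evaluateSelector <- function(sel, graph, proteinIds) {
  st <- graph@statements
  nodes <- graph@nodes$id
  if (sel$kind == "term") {
    if (!sel$term %in% nodes) {
      stop("query term not in graph: ", sel$term)
    }
    terms <- if (isTRUE(sel$useDescendants)) {
      termDescendants(graph, sel$term)
    } else sel$term
    hits <- st$predicate == sel$predicate & st$object %in% terms
    intersect(unique(st$subject[hits]), proteinIds)
  } else {
    types <- NULL
    if (!is.null(sel$interactionType)) {
      if (!sel$interactionType %in% nodes) {
        stop("interaction type not in graph: ", sel$interactionType)
      }
      types <- if (isTRUE(sel$useDescendants)) {
        termDescendants(graph, sel$interactionType)
      } else sel$interactionType
    }
    part <- st[st$predicate == "has_participant", , drop = FALSE]
    inter <- unique(part$subject)
    if (!is.null(types)) {
      ty <- st[st$predicate == "has_interaction_type" &
                 st$object %in% types, , drop = FALSE]
      inter <- intersect(inter, unique(ty$subject))
    }
    if (!is.null(sel$partner)) {
      if (!sel$partner %in% nodes) {
        stop("interaction partner not in graph: ", sel$partner)
      }
      withPartner <- unique(part$subject[part$object == sel$partner])
      inter <- intersect(inter, withPartner)
    }
    hits <- unique(part$object[part$subject %in% inter])
    hits <- setdiff(hits, sel$partner)
    intersect(hits, proteinIds)
  }
}

evaluateExpression <- function(expr, graph, proteinIds, clauseHits) {
  if (is.null(expr)) {
    return(list(matched = character(), clauseHits = clauseHits))
  }
  if (inherits(expr, "QuerySelector")) {
    m <- evaluateSelector(expr, graph, proteinIds)
    clauseHits[[expr$label]] <- m
    return(list(matched = m, clauseHits = clauseHits))
  }
  if (!length(expr$children)) {
    return(list(matched = character(), clauseHits = clauseHits))
  }
  sets <- list()
  for (ch in expr$children) {
    res <- evaluateExpression(ch, graph, proteinIds, clauseHits)
    clauseHits <- res$clauseHits
    sets[[length(sets) + 1L]] <- res$matched
  }
  matched <- if (expr$kind == "and") Reduce(intersect, sets)
             else Reduce(union, sets)
  list(matched = matched, clauseHits = clauseHits)
}

#' Evaluate a query template against a graph
#'
#' Returns one row per matching protein, sorted by CURIE, with the labels
#' of the leaf clauses that protein satisfies (`;`-separated). Evaluation
#' uses whatever statements the graph holds, so running the same template
#' against the asserted record and against the closure realises the
#' asserted/inferred comparison.
#'
#' @param template A [queryTemplate()].
#' @param graph A [KnowledgeGraph-class].
#' @return `data.frame` with columns `protein`, `clauses`.
#' @export
evaluateTemplate <- function(template, graph) {
  stopifnot(inherits(template, "QueryTemplate"))
  nd <- graph@nodes
  proteinIds <- nd$id[nd$category == "protein"]
  res <- evaluateExpression(template$expression, graph, proteinIds, list())
  matched <- res$matched
  if (!is.null(template$taxon)) {
    st <- graph@statements
    inTaxon <- unique(st$subject[st$predicate == "in_taxon" &
                                   st$object == template$taxon])
    matched <- intersect(matched, inTaxon)
  }
  matched <- sort(matched)
  clauses <- vapply(matched, function(p) {
    labs <- names(res$clauseHits)[vapply(res$clauseHits,
                                         function(s) p %in% s, logical(1))]
    paste(labs, collapse = ";")
  }, character(1))
  data.frame(protein = matched, clauses = unname(clauses),
             stringsAsFactors = FALSE)
}

#' Default role-to-CURIE bindings for the built-in templates
#'
#' All identifiers in the built-in templates are parameters; these are the
#' published defaults (CREB1 `UniProtKB:P16220`, TCF7L2
#' `UniProtKB:Q9NQB0`, plus the GO/MI/KEGG terms each clause targets).
#' Override any subset to retarget the templates, e.g. at a synthetic
#' graph.
#'
#' @return Named character vector of role bindings.
#' @export
defaultTargetIds <- function() {
  c(creb1 = "UniProtKB:P16220",
    tcf7l2 = "UniProtKB:Q9NQB0",
    pos_reg_creb_activity = "GO:0032793",
    creb_binding_function = "GO:0008140",
    direct_interaction = "MI:0407",
    physical_association = "MI:0914",
    pos_reg_dbtf_activity = "GO:0051091",
    neg_reg_creb_activity = "GO:0032792",
    neg_reg_dbtf_activity = "GO:0043433",
    hat_activity = "GO:0004402",
    hdac_activity = "GO:0004407",
    reg_dbtf_activity = "GO:0051090",
    neg_reg_nfkb_activity = "GO:0032088",
    ubiquitin_ligase_complex = "GO:0000151",
    ubiquitin_binding = "GO:0043130",
    ubiquitination_reaction = "MI:0220",
    ubiquitin_proteolysis_pathway = "KEGG:ko04120")
}

#' The built-in regulatory-candidate query templates (Q1–Q5)
#'
#' Parameterised reconstructions of the five use-case queries:
#' * **Q1** (activators of CREB1): proteins annotated to positive
#'   regulation of CREB transcription-factor activity (clause A), or with
#'   the CREB-binding molecular function (D), or directly interacting with
#'   CREB1 (C, `MI:0407`), or annotated to the broader positive regulation
#'   of DbTF activity *and* physically associated with CREB1 (B ∧
#'   `MI:0914`).
#' * **Q2** (repressors of CREB1): the two negative-regulation terms,
#'   union; optionally conjoined with a CREB1 interaction clause.
#' * **Q3** (chromatin modifiers): histone acetyltransferase or
#'   deacetylase activity, and regulation of DbTF activity, and an
#'   interaction with CREB1 (any type).
#' * **Q4** (NFκB repressors undergoing proteasomal degradation): the
#'   central negative-regulation-of-NFκB term intersected with the union
#'   of four degradation-related clauses (ubiquitin ligase complex,
#'   ubiquitin binding, ubiquitination-reaction interaction type, and the
#'   ubiquitin-mediated proteolysis pathway). `q4Mode = "union"` exposes
#'   the alternative pure-union reading.
#' * **Q5** (dual-role partners of TCF7L2): proteins interacting with
#'   TCF7L2 annotated to both the negative and the positive regulation of
#'   DbTF activity terms.
#'
#' @param targetIds Named character vector overriding any subset of
#'   [defaultTargetIds()]. Roles set to `NA`/empty raise an error.
#' @param q2InteractionConjunct Add an interacts-with-CREB1 conjunct to Q2.
#' @param q4Mode `"intersect"` (central term AND degradation union) or
#'   `"union"`.
#' @return Named list of [queryTemplate()] objects `Q1`..`Q5`.
#' @export
builtinTemplates <- function(targetIds = character(),
                             q2InteractionConjunct = FALSE,
                             q4Mode = c("intersect", "union")) {
  q4Mode <- match.arg(q4Mode)
  ids <- defaultTargetIds()
  if (length(targetIds)) {
    unknown <- setdiff(names(targetIds), names(ids))
    if (length(unknown)) stop("unknown target roles: ", toString(unknown))
    ids[names(targetIds)] <- targetIds
  }
  bad <- names(ids)[is.na(ids) | !nzchar(ids)]
  if (length(bad)) stop("missing target ids for roles: ", toString(bad))

  A <- termSelector("participates_in", ids[["pos_reg_creb_activity"]],
                    label = "A")
  B <- termSelector("participates_in", ids[["pos_reg_dbtf_activity"]],
                    label = "B")
  C <- interactionSelector(ids[["creb1"]], ids[["direct_interaction"]],
                           label = "C")
  D <- termSelector("has_function", ids[["creb_binding_function"]],
                    label = "D")
  Bassoc <- interactionSelector(ids[["creb1"]],
                                ids[["physical_association"]],
                                label = "B-assoc")
  q1 <- queryTemplate("Q1", qOr(A, D, C, qAnd(B, Bassoc)))

  q2expr <- qOr(
    termSelector("participates_in", ids[["neg_reg_creb_activity"]],
                 label = "neg-reg-CREB"),
    termSelector("participates_in", ids[["neg_reg_dbtf_activity"]],
                 label = "neg-reg-DbTF"))
  if (q2InteractionConjunct) {
    q2expr <- qAnd(q2expr, interactionSelector(ids[["creb1"]],
                                               label = "CREB1-interaction"))
  }
  q2 <- queryTemplate("Q2", q2expr)

  q3 <- queryTemplate("Q3", qAnd(
    qOr(termSelector("has_function", ids[["hat_activity"]], label = "HAT"),
        termSelector("has_function", ids[["hdac_activity"]],
                     label = "HDAC")),
    termSelector("participates_in", ids[["reg_dbtf_activity"]],
                 label = "reg-DbTF"),
    interactionSelector(ids[["creb1"]], label = "CREB1-interaction")))

  degradation <- qOr(
    termSelector("located_in", ids[["ubiquitin_ligase_complex"]],
                 label = "ubiquitin-ligase-complex"),
    termSelector("has_function", ids[["ubiquitin_binding"]],
                 label = "ubiquitin-binding"),
    interactionSelector(interactionType = ids[["ubiquitination_reaction"]],
                        label = "ubiquitination-interaction"),
    termSelector("member_of_pathway",
                 ids[["ubiquitin_proteolysis_pathway"]],
                 label = "ubiquitin-proteolysis-pathway"))
  central <- termSelector("participates_in", ids[["neg_reg_nfkb_activity"]],
                          label = "neg-reg-NFkB")
  q4 <- queryTemplate("Q4", if (q4Mode == "intersect") {
    qAnd(central, degradation)
  } else {
    qOr(central, degradation)
  })

  q5 <- queryTemplate("Q5", qAnd(
    interactionSelector(ids[["tcf7l2"]], label = "TCF7L2-interaction"),
    termSelector("participates_in", ids[["neg_reg_dbtf_activity"]],
                 label = "neg-reg-DbTF"),
    termSelector("participates_in", ids[["pos_reg_dbtf_activity"]],
                 label = "pos-reg-DbTF")))

  list(Q1 = q1, Q2 = q2, Q3 = q3, Q4 = q4, Q5 = q5)
}

#' Restrict candidates to the DbTF catalog
#'
#' Plain intersection with the (ID-mapped) DNA-binding transcription-factor
#' catalog, sorted.
#'
#' @param candidates Character vector of protein CURIEs.
#' @param catalog Character vector of catalog CURIEs.
#' @return Sorted character vector.
#' @export
filterDbtf <- function(candidates, catalog) {
  sort(intersect(unique(candidates), unique(catalog)))
}

#' Shared target genes of two regulator sets
#'
#' Finds target genes regulated by both a novel candidate DbTF and a core
#' (query) DbTF: one row per `(novel, core, target)` combination where some
#' edge `novel -> target` and some edge `core -> target` exist. The
#' regulatory mode is taken from the novel edge; duplicate combinations
#' arising from several source databases collapse to one row with the
#' source tags concatenated (`;`-separated, sorted). Rows are ordered by
#' `(novel, core, target)`.
#'
#' @param novelDbtfs,coreDbtfs Character vectors of regulator identifiers.
#' @param edges Regulatory-edge `data.frame` (see [readRegulatoryEdges()]).
#' @return `data.frame` with columns `novel`, `mode`, `core`,
#'   `target_gene`, `sources`.
#' @export
sharedTargets <- function(novelDbtfs, coreDbtfs, edges) {
  stopifnot(nrow(edges) > 0L)
  novel <- edges[edges$regulator %in% novelDbtfs, , drop = FALSE]
  core <- edges[edges$regulator %in% coreDbtfs, , drop = FALSE]
  if (!nrow(novel) || !nrow(core)) {
    return(data.frame(novel = character(), mode = character(),
                      core = character(), target_gene = character(),
                      sources = character(), stringsAsFactors = FALSE))
  }
  m <- merge(novel[c("regulator", "target_gene", "mode", "source_db")],
             core[c("regulator", "target_gene")],
             by = "target_gene", suffixes = c(".novel", ".core"))
  if (!nrow(m)) {
    return(data.frame(novel = character(), mode = character(),
                      core = character(), target_gene = character(),
                      sources = character(), stringsAsFactors = FALSE))
  }
  key <- paste(m$regulator.novel, m$regulator.core, m$target_gene,
               sep = "\r")
  agg <- lapply(split(m, key), function(grp) {
    data.frame(novel = grp$regulator.novel[1],
               mode = paste(sort(unique(grp$mode)), collapse = ";"),
               core = grp$regulator.core[1],
               target_gene = grp$target_gene[1],
               sources = paste(sort(unique(grp$source_db)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$novel, out$core, out$target_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition query hits by statement provenance
#'
#' Evaluates a template three ways — against the asserted record, against
#' the inference layer alone, and against the full closure — and classifies
#' every closure hit: `asserted_only` (retrievable from direct statements
#' but not from inferred ones alone), `both` (retrievable either way), and
#' `inferred_only` (unreachable without inference, including matches that
#' mix asserted and inferred statements). The classes are disjoint and sum
#' to the closure hit count.
#'
#' @param template A [queryTemplate()].
#' @param assertedGraph The graph of asserted statements.
#' @param closedGraph Its closure (see [computeClosure()]); every asserted
#'   statement must be present, else an error is raised.
#' @return A list with the three CURIE vectors (`asserted_only`, `both`,
#'   `inferred_only`), a `classes` data.frame (columns `protein`,
#'   `provenance_class`), and `counts` (named integer vector including
#'   `total`).
#' @export
provenancePartition <- function(template, assertedGraph, closedGraph) {
  aSt <- assertedStatements(assertedGraph)
  cSt <- closedGraph@statements
  missing <- !statementKey(aSt) %in% statementKey(cSt)
  if (any(missing)) {
    stop("closedGraph is not a closure of assertedGraph: ",
         sum(missing), " asserted statement(s) missing")
  }
  onlyProvenance <- function(g, prov) {
    g@statements <- kgStatements(g, provenance = prov)
    g
  }
  A <- evaluateTemplate(template, onlyProvenance(closedGraph,
                                                 "asserted"))$protein
  I <- evaluateTemplate(template, onlyProvenance(closedGraph,
                                                 "inferred"))$protein
  M <- evaluateTemplate(template, closedGraph)$protein
  assertedOnly <- setdiff(A, I)
  both <- intersect(A, I)
  inferredOnly <- setdiff(M, A)
  classes <- data.frame(
    protein = c(assertedOnly, both, inferredOnly),
    provenance_class = rep(c("asserted_only", "both", "inferred_only"),
                           c(length(assertedOnly), length(both),
                             length(inferredOnly))),
    stringsAsFactors = FALSE)
  classes <- classes[order(classes$protein), , drop = FALSE]
  rownames(classes) <- NULL
  list(asserted_only = sort(assertedOnly), both = sort(both),
       inferred_only = sort(inferredOnly), classes = classes,
       counts = c(asserted_only = length(assertedOnly),
                  both = length(both),
                  inferred_only = length(inferredOnly),
                  total = length(M)))
}
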