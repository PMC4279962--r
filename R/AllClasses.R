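#' @import methods
NULL

## Internal canonical empty tables. All graph content lives in plain
## data.frames (character columns, no factors) so that set operations on
## statements stay vectorised.

emptyNodeTable <- function() {
  data.frame(id = character(), label = character(), category = character(),
             stringsAsFactors = FALSE)
}

emptyRelationTable <- function() {
  data.frame(id = character(), name = character(),
             transitive = logical(), reflexive = logical(),
             priority_over_subsumption = logical(),
             stringsAsFactors = FALSE)
}

emptySuperRelationTable <- function() {
  data.frame(relation = character(), superrelation = character(),
             stringsAsFactors = FALSE)
}

emptyCompositionTable <- function() {
  data.frame(relation = character(), second = character(),
             produces = character(), stringsAsFactors = FALSE)
}

emptyStatementTable <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), provenance = character(),
             source = character(), stringsAsFactors = FALSE)
}

statementKey <- function(statements) {
  paste(statements$subject, statements$predicate, statements$object,
        sep = "\r")
}

#' KnowledgeGraph: typed nodes plus relation-typed statements
#'
#' The central container of the package. A `KnowledgeGraph` holds a set of
#' typed term nodes (ontology classes, proteins, genes, pathways, reified
#' interactions, modified residues, taxa), a set of relation types carrying
#' the metadata that drives inference (transitivity, reflexivity,
#' superrelations, compositions, priority over subsumption), and a set of
#' subject--predicate--object statements, each tagged with `asserted` or
#' `inferred` provenance and a free-text source.
#'
#' The graph is closed under reference: every CURIE used as a statement
#' subject or object must be a declared node, and every predicate a declared
#' relation. A `(subject, predicate, object)` triple is unique regardless of
#' provenance; on collision the asserted version wins.
#'
#' @slot name Graph name (closure variants conventionally append `-tc`).
#' @slot nodes `data.frame` with columns `id`, `label`, `category`.
#' @slot relations `data.frame` with columns `id`, `name`, `transitive`,
#'   `reflexive`, `priority_over_subsumption`.
#' @slot superRelations `data.frame` with columns `relation`,
#'   `superrelation` (both relation ids).
#' @slot compositions `data.frame` with columns `relation`, `second`,
#'   `produces`: a statement `x r y` composed with `y s z` yields `x t z`
#'   when `(r, s, t)` is a declared composition.
#' @slot statements `data.frame` with columns `subject`, `predicate`,
#'   `object`, `provenance`, `source`.
#'
#' @seealso [knowledgeGraph()] for construction, [kgStatements()] and friends
#'   for access, [computeClosure()] for inference.
#' @export
setClass("KnowledgeGraph",
  slots = c(
    name = "character",
    nodes = "data.frame",
    relations = "data.frame",
    superRelations = "data.frame",
    compositions = "data.frame",
    statements = "data.frame"
  ),
  prototype = list(
    name = "kg",
    nodes = emptyNodeTable(),
    relations = emptyRelationTable(),
    superRelations = emptySuperRelationTable(),
    compositions = emptyCompositionTable(),
    statements = emptyStatementTable()
  )
)

setValidity("KnowledgeGraph", function(object) {
  msgs <- character()
  nd <- object@nodes; rl <- object@relations; st <- object@statements
  if (length(object@name) != 1L) msgs <- c(msgs, "name must be length 1")
  if (!all(c("id", "label", "category") %in% names(nd))) {
    msgs <- c(msgs, "nodes must have columns id, label, category")
  } else {
    if (anyDuplicated(nd$id)) msgs <- c(msgs, "duplicate node ids")
    bad <- setdiff(unique(nd$category), kgCategories())
    if (length(bad)) {
      msgs <- c(msgs, paste("unknown node categories:", toString(bad)))
    }
  }
  if (anyDuplicated(rl$id)) msgs <- c(msgs, "duplicate relation ids")
  sr <- object@superRelations
  if (nrow(sr)) {
    undecl <- setdiff(unique(c(sr$relation, sr$superrelation)), rl$id)
    if (length(undecl)) {
      msgs <- c(msgs, paste("superrelations reference undeclared relations:",
                            toString(undecl)))
    }
    if (any(sr$relation == sr$superrelation)) {
      msgs <- c(msgs, "a relation cannot be its own superrelation")
    }
  }
  cp <- object@compositions
  if (nrow(cp)) {
    undecl <- setdiff(unique(c(cp$relation, cp$second, cp$produces)), rl$id)
    if (length(undecl)) {
      msgs <- c(msgs, paste("compositions reference undeclared relations:",
                            toString(undecl)))
    }
  }
  if (nrow(st)) {
    if (!all(st$provenance %in% c("asserted", "inferred"))) {
      msgs <- c(msgs, "statement provenance must be asserted or inferred")
    }
    missN <- setdiff(unique(c(st$subject, st$object)), nd$id)
    if (length(missN)) {
      msgs <- c(msgs, paste("statements reference undeclared nodes:",
                            toString(utils::head(missN, 5))))
    }
    missR <- setdiff(unique(st$predicate), rl$id)
    if (length(missR)) {
      msgs <- c(msgs, paste("statements reference undeclared relations:",
                            toString(missR)))
    }
    if (anyDuplicated(statementKey(st))) {
      msgs <- c(msgs, "duplicate (subject, predicate, object) statements")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ClosureResult: outcome of computing a total closure
#'
#' Returned by [computeClosure()]. Carries the closed graph (asserted plus
#' inferred statements; graph name suffixed `-tc`), the asserted and inferred
#' statement counts, the fold increase
#' `(asserted + inferred) / asserted`, and the number of statements first
#' produced by each inference rule.
#'
#' @slot graph The closed [KnowledgeGraph-class].
#' @slot assertedCount Number of asserted statements (unchanged from input).
#' @slot inferredCount Number of statements added by inference.
#' @slot foldIncrease `(assertedCount + inferredCount) / assertedCount`.
#' @slot perRuleCounts Named integer vector over the five rule kinds; each
#'   inferred statement is counted once, under the first rule that produced
#'   it.
#' @export
setClass("ClosureResult",
  slots = c(
    graph = "KnowledgeGraph",
    assertedCount = "integer",
    inferredCount = "integer",
    foldIncrease = "numeric",
    perRuleCounts = "integer"
  )
)

setValidity("ClosureResult", function(object) {
  msgs <- character()
  if (object@inferredCount != sum(object@perRuleCounts)) {
    msgs <- c(msgs, "inferredCount must equal the sum of perRuleCounts")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ClosureResult `$` access to slots for convenience.
#' @param x,name Object and slot name.
#' @export
setMethod("$", "ClosureResult", function(x, name) slot(x, name))
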