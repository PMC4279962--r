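#' Accessors for KnowledgeGraph objects
#'
#' Slot access goes through accessors, never `@`. `kgStatements()` optionally
#' filters by provenance; `assertedStatements()` and `inferredStatements()`
#' are shorthands.
#'
#' @param x A [KnowledgeGraph-class].
#' @param provenance Optional: `"asserted"` or `"inferred"` to filter
#'   statements.
#' @return The corresponding slot (`data.frame`s for tables, a string for the
#'   name).
#' @name KnowledgeGraph-accessors
#' @examples
#' g <- assembleULO()
#' kgName(g)
#' head(kgNodes(g))
#' nrow(kgStatements(g, provenance = "asserted"))
NULL

#' @rdname KnowledgeGraph-accessors
#' @export
setGeneric("kgName", function(x) standardGeneric("kgName"))

#' @rdname KnowledgeGraph-accessors
#' @export
setGeneric("kgNodes", function(x) standardGeneric("kgNodes"))

#' @rdname KnowledgeGraph-accessors
#' @export
setGeneric("kgRelations", function(x) standardGeneric("kgRelations"))

#' @rdname KnowledgeGraph-accessors
#' @export
setGeneric("kgSuperRelations", function(x) standardGeneric("kgSuperRelations"))

#' @rdname KnowledgeGraph-accessors
#' @export
setGeneric("kgCompositions", function(x) standardGeneric("kgCompositions"))

#' @rdname KnowledgeGraph-accessors
#' @export
setGeneric("kgStatements", function(x, provenance = NULL)
  standardGeneric("kgStatements"))

#' @rdname KnowledgeGraph-accessors
#' @export
setMethod("kgName", "KnowledgeGraph", function(x) x@name)

#' @rdname KnowledgeGraph-accessors
#' @export
setMethod("kgNodes", "KnowledgeGraph", function(x) x@nodes)

#' @rdname KnowledgeGraph-accessors
#' @export
setMethod("kgRelations", "KnowledgeGraph", function(x) x@relations)

#' @rdname KnowledgeGraph-accessors
#' @export
setMethod("kgSuperRelations", "KnowledgeGraph", function(x) x@superRelations)

#' @rdname KnowledgeGraph-accessors
#' @export
setMethod("kgCompositions", "KnowledgeGraph", function(x) x@compositions)

#' @rdname KnowledgeGraph-accessors
#' @export
setMethod("kgStatements", "KnowledgeGraph", function(x, provenance = NULL) {
  st <- x@statements
  if (!is.null(provenance)) {
    provenance <- match.arg(provenance, c("asserted", "inferred"))
    st <- st[st$provenance == provenance, , drop = FALSE]
    rownames(st) <- NULL
  }
  st
})

#' @rdname KnowledgeGraph-accessors
#' @export
assertedStatements <- function(x) kgStatements(x, provenance = "asserted")

#' @rdname KnowledgeGraph-accessors
#' @export
inferredStatements <- function(x) kgStatements(x, provenance = "inferred")

setMethod("show", "KnowledgeGraph", function(object) {
  st <- object@statements
  cat("KnowledgeGraph \"", object@name, "\"\n", sep = "")
  cat("  nodes:      ", nrow(object@nodes), sep = "")
  if (nrow(object@nodes)) {
    tab <- sort(table(object@nodes$category), decreasing = TRUE)
    cat(" (", paste0(names(tab), ": ", tab, collapse = ", "), ")", sep = "")
  }
  cat("\n  relations:  ", nrow(object@relations), "\n", sep = "")
  cat("  statements: ", nrow(st),
      " (asserted: ", sum(st$provenance == "asserted"),
      ", inferred: ", sum(st$provenance == "inferred"), ")\n", sep = "")
})

setMethod("show", "ClosureResult", function(object) {
  cat("ClosureResult for \"", kgName(object@graph), "\"\n", sep = "")
  cat("  asserted:     ", object@assertedCount, "\n", sep = "")
  cat("  inferred:     ", object@inferredCount, "\n", sep = "")
  cat("  fold increase:", format(object@foldIncrease, digits = 4), "\n")
  pr <- object@perRuleCounts
  pr <- pr[pr > 0]
  if (length(pr)) {
    cat("  by rule:      ",
        paste0(names(pr), " = ", pr, collapse = ", "), "\n", sep = "")
  }
})
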