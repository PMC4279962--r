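## Candidate classification and target-gene assessment: the final,
## evidence-driven step that turns query output into a ranked worklist.

## Case-insensitive boolean lookup: absence means FALSE.
evidenceFlag <- function(entities, table, column) {
  if (is.null(table) || !nrow(table)) return(rep(FALSE, length(entities)))
  idx <- match(toupper(entities), toupper(table$entity))
  out <- table[[column]][idx]
  out[is.na(out)] <- FALSE
  out
}

#' Classify candidate regulators
#'
#' Applies the documented/novel classification:
#' * `a` — already a member of the existing network map (regardless of any
#'   other evidence);
#' * otherwise `b`, split by expression responsiveness in the model system:
#'   responsive candidates form `b1`, refined by literature into `b1i`
#'   (known responsive to other stimuli — the most promising novel
#'   candidates) and `b1j` (no such report); non-responsive candidates are
#'   `b_other`.
#'
#' Priorities are explicit integers (`a` = 0, `b1i` = 1, `b1j` = 2,
#' `b_other` = 3) so downstream sorting is total and stable. The four
#' categories partition the candidate set.
#'
#' @param candidates Character vector of candidate identifiers.
#' @param membership Character vector of documented network members, or a
#'   `data.frame` with a `member` column (see [readNetworkMembership()]).
#' @param expression Expression-evidence `data.frame` (`entity`,
#'   `expressed`, `responsive`); absent entities count as all-FALSE.
#' @param literature Literature-evidence `data.frame` (`entity`,
#'   `responsive_to_other_stimuli`); absent entities count as FALSE.
#' @return `data.frame` with columns `protein`, `category`, `priority`,
#'   ordered by priority then identifier.
#' @export
classifyCandidates <- function(candidates, membership = character(),
                               expression = NULL, literature = NULL) {
  if (is.data.frame(membership)) membership <- membership$member
  candidates <- unique(candidates)
  if (!length(candidates)) {
    return(data.frame(protein = character(), category = character(),
                      priority = integer(), stringsAsFactors = FALSE))
  }
  isMember <- toupper(candidates) %in% toupper(membership)
  responsive <- evidenceFlag(candidates, expression, "responsive")
  litKnown <- evidenceFlag(candidates, literature,
                           "responsive_to_other_stimuli")
  category <- ifelse(isMember, "a",
                ifelse(responsive,
                       ifelse(litKnown, "b1i", "b1j"),
                       "b_other"))
  priority <- c(a = 0L, b1i = 1L, b1j = 2L, b_other = 3L)[category]
  out <- data.frame(protein = candidates, category = category,
                    priority = unname(priority), stringsAsFactors = FALSE)
  out <- out[order(out$priority, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assess shared target genes against expression evidence
#'
#' Annotates each shared-target row (see [sharedTargets()]) with the model
#' system's evidence for the target gene: whether it is expressed and
#' whether its expression responds to the stimulus. A target is a
#' *candidate* when it is both expressed and responsive; a candidate is
#' additionally *dual-supported* when its novel regulator is itself
#' expressed in the model system (targets of expressed regulators carry
#' greater weight). Gene symbols are matched case-insensitively.
#'
#' @param rows Shared-target `data.frame` (columns `novel`, `mode`, `core`,
#'   `target_gene`, ...).
#' @param expression Expression evidence for target genes (`entity`,
#'   `expressed`, `responsive`).
#' @param regulatorExpression Expression evidence for the novel regulators
#'   (same columns; only `expressed` is used).
#' @return The input rows with added logical columns `expressed`,
#'   `responsive`, `candidate`, `regulator_expressed`, `dual_supported`.
#' @export
assessTargetGenes <- function(rows, expression,
                              regulatorExpression = NULL) {
  rows$expressed <- evidenceFlag(rows$target_gene, expression, "expressed")
  rows$responsive <- evidenceFlag(rows$target_gene, expression,
                                  "responsive")
  rows$candidate <- rows$expressed & rows$responsive
  rows$regulator_expressed <- evidenceFlag(rows$novel, regulatorExpression,
                                           "expressed")
  rows$dual_supported <- rows$candidate & rows$regulator_expressed
  rows
}
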