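#' Compact identifiers (CURIEs)
#'
#' Every entity in a knowledge graph is identified by a CURIE, a
#' `namespace:local_id` pair. Two rendering dialects are supported: the OBO
#' dialect `"GO:0010467"` (colon separator) and the triple dialect
#' `"GO_0010467"` (underscore separator, used for N-Triples URIs). Internally
#' CURIEs are stored in the OBO dialect; the two renderings round-trip
#' losslessly because the namespace never contains `_` or `:` and the local id
#' is whitespace-free.
#'
#' @param namespace Character vector of namespaces (non-empty strings).
#' @param local_id Character vector of local identifiers. Whitespace is
#'   replaced by underscores at construction, matching the convention used for
#'   modified-residue identifiers built from free-text names.
#' @return `curie()` returns a character vector of CURIEs in the OBO dialect.
#' @examples
#' curie("GO", "0010467")
#' curie("SSB", "phospho serine 133")  # spaces become underscores
#' @export
curie <- function(namespace, local_id) {
  namespace <- as.character(namespace)
  local_id <- as.character(local_id)
  if (!length(namespace) || !length(local_id)) return(character())
  if (any(!nzchar(namespace)) || anyNA(namespace)) {
    stop("CURIE namespace must be non-empty")
  }
  if (any(grepl("[_:]", namespace))) {
    stop("CURIE namespace must not contain ':' or '_'")
  }
  local_id <- gsub("[[:space:]]+", "_", trimws(local_id))
  if (any(!nzchar(local_id))) stop("CURIE local id must be non-empty")
  paste0(namespace, ":", local_id)
}

#' @rdname curie
#' @param x Character vector of CURIEs (OBO dialect).
#' @return `curieNamespace()` and `curieLocal()` return the two components.
#' @export
curieNamespace <- function(x) sub(":.*$", "", x)

#' @rdname curie
#' @export
curieLocal <- function(x) sub("^[^:]+:", "", x)

#' @rdname curie
#' @return `curieToTriple()` renders CURIEs in the triple dialect
#'   (`namespace_local_id`); `curieFromTriple()` parses that dialect back,
#'   splitting at the first underscore.
#' @export
curieToTriple <- function(x) sub(":", "_", x, fixed = TRUE)

#' @rdname curie
#' @export
curieFromTriple <- function(x) sub("_", ":", x, fixed = TRUE)

#' Term category implied by a CURIE namespace
#'
#' Node categories are a pure function of the identifier namespace:
#' `UniProtKB` identifies proteins, `KEGG` pathways, `NCBIGene` genes,
#' `NCBITaxon` taxa, `SSB` modified residues and `intact` reified
#' protein-protein interactions. Any other namespace (GO, MI, synthetic
#' ontology namespaces, ...) denotes an ontology class.
#'
#' @param namespace Character vector of namespaces, or full CURIEs (anything
#'   containing `:` is reduced to its namespace first).
#' @return Character vector of categories.
#' @examples
#' termCategory(c("UniProtKB:P16220", "GO:0010467", "KEGG:ko04120"))
#' @export
termCategory <- function(namespace) {
  ns <- ifelse(grepl(":", namespace), curieNamespace(namespace), namespace)
  map <- c(
    UniProtKB = "protein", KEGG = "pathway", NCBIGene = "gene",
    NCBITaxon = "taxon", SSB = "modified_residue", intact = "interaction"
  )
  out <- unname(map[ns])
  out[is.na(out)] <- "ontology_class"
  out
}

#' All node categories recognised by the graph model
#' @return Character vector of the seven category names.
#' @keywords internal
kgCategories <- function() {
  c("ontology_class", "protein", "gene", "pathway", "interaction",
    "modified_residue", "taxon")
}
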