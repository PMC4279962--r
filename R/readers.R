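## Readers for the standard flat formats feeding the knowledge graph:
## GAF 2.x annotation files, PSI-MI TAB 2.5 interaction files, and headered
## TSV tables (ID mappings, pathways, orthology, regulatory edges, DbTF
## catalogs, expression evidence). Malformed rows are skipped and counted;
## the count is attached as attr(result, "skipped").

readerLines <- function(stream) {
  if (is.character(stream) && length(stream) == 1L && file.exists(stream)) {
    readLines(stream, warn = FALSE)
  } else if (inherits(stream, "connection")) {
    readLines(stream, warn = FALSE)
  } else {
    as.character(stream)
  }
}

withSkipped <- function(df, skipped, what) {
  attr(df, "skipped") <- skipped
  if (skipped > 0L) {
    warning(skipped, " malformed ", what, " row(s) skipped", call. = FALSE)
  }
  df
}

#' Read a GAF 2.x gene-association file
#'
#' Lines starting with `!` are comments. Each record yields one annotation:
#' the protein CURIE is built from the DB and DB Object ID columns, the
#' ontology term is taken from the GO ID column, the aspect from the Aspect
#' column (`P`, `F` or `C`), plus evidence code and taxon (`taxon:9606`
#' becomes `NCBITaxon:9606`; only the first taxon of a multi-taxon field is
#' kept). Rows with fewer than 15 columns, an aspect outside `P/F/C`, or an
#' ontology id without a namespace are skipped and counted.
#'
#' @param stream File path, connection or character vector of lines.
#' @return `data.frame` with columns `protein`, `go_term`, `aspect`,
#'   `evidence_code`, `taxon`; the number of skipped rows is attached as
#'   `attr(, "skipped")`.
#' @export
readGAF <- function(stream) {
  lines <- readerLines(stream)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  empty <- data.frame(protein = character(), go_term = character(),
                      aspect = character(), evidence_code = character(),
                      taxon = character(), stringsAsFactors = FALSE)
  if (!length(lines)) return(withSkipped(empty, 0L, "GAF"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  skipped <- 0L; rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    ok <- length(f) >= 15L && nzchar(f[1]) && nzchar(f[2]) &&
      grepl(":", f[5]) && f[9] %in% c("P", "F", "C")
    if (!ok) { skipped <- skipped + 1L; next }
    taxon <- strsplit(f[13], "|", fixed = TRUE)[[1]][1]
    taxon <- sub("^taxon:", "NCBITaxon:", taxon)
    rows[[i]] <- c(curie(f[1], f[2]), f[5], f[9], f[7], taxon)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(withSkipped(empty, skipped, "GAF"))
  m <- do.call(rbind, rows)
  out <- data.frame(protein = m[, 1], go_term = m[, 2], aspect = m[, 3],
                    evidence_code = m[, 4], taxon = m[, 5],
                    stringsAsFactors = FALSE)
  withSkipped(out, skipped, "GAF")
}

## "uniprotkb:P16220|intact:EBI-1" -> "UniProtKB:P16220" (first alternative)
parseMitabId <- function(x) {
  first <- vapply(strsplit(x, "|", fixed = TRUE),
                  function(p) p[1], character(1))
  ns <- sub(":.*$", "", first)
  id <- sub("^[^:]+:", "", first)
  ns[ns == "uniprotkb"] <- "UniProtKB"
  ifelse(nzchar(ns) & nzchar(id) & ns != first, paste0(ns, ":", id),
         NA_character_)
}

#' Read a PSI-MI TAB 2.5 interaction file
#'
#' Uses the minimal column set: interactor A and B identifiers (columns 1
#' and 2; the first alternative of a `|`-separated list, with `uniprotkb`
#' normalised to `UniProtKB`), the interaction type (column 12, e.g.
#' `psi-mi:"MI:0407"(direct interaction)`, reduced to the `MI:...` CURIE)
#' and the interaction identifier (column 14, `intact` namespace). A header
#' line starting with `#` is ignored. Rows missing any of these fields are
#' skipped and counted.
#'
#' @inheritParams readGAF
#' @return `data.frame` with columns `interaction_id`, `participant_a`,
#'   `participant_b`, `interaction_type`; skipped-row count attached as
#'   `attr(, "skipped")`.
#' @export
readMITAB <- function(stream) {
  lines <- readerLines(stream)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  empty <- data.frame(interaction_id = character(),
                      participant_a = character(),
                      participant_b = character(),
                      interaction_type = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(withSkipped(empty, 0L, "MI-TAB"))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  skipped <- 0L; rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 14L) { skipped <- skipped + 1L; next }
    a <- parseMitabId(f[1]); b <- parseMitabId(f[2])
    ty <- regmatches(f[12], regexpr("MI:[0-9]+", f[12]))
    iid <- parseMitabId(f[14])
    if (is.na(a) || is.na(b) || !length(ty) || is.na(iid)) {
      skipped <- skipped + 1L; next
    }
    rows[[i]] <- c(iid, a, b, ty)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(withSkipped(empty, skipped, "MI-TAB"))
  m <- do.call(rbind, rows)
  out <- data.frame(interaction_id = m[, 1], participant_a = m[, 2],
                    participant_b = m[, 3], interaction_type = m[, 4],
                    stringsAsFactors = FALSE)
  withSkipped(out, skipped, "MI-TAB")
}

#' Read a headered TSV table against a declared schema
#'
#' UTF-8, tab-delimited, one header row. All `schema` columns must be
#' present (extra columns are kept); a mismatch raises an error naming the
#' missing columns.
#'
#' @inheritParams readGAF
#' @param schema Character vector of required column names.
#' @return `data.frame` with character columns.
#' @export
readTable <- function(stream, schema) {
  lines <- readerLines(stream)
  if (!length(lines)) stop("empty table stream")
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE, quote = "")
  missing <- setdiff(schema, names(df))
  if (length(missing)) {
    stop("table is missing required column(s): ", toString(missing))
  }
  df
}

asFlag <- function(x) toupper(trimws(x)) %in% c("TRUE", "YES", "1", "Y")

#' Typed TSV readers
#'
#' Thin wrappers over [readTable()] with fixed schemas, one per integrated
#' resource:
#' \describe{
#'   \item{`readIdMapping`}{columns `source_ns`, `source_id`, `target` — the
#'     identifier-normalisation table; `target` is the canonical protein
#'     CURIE.}
#'   \item{`readPathways`}{columns `protein`, `pathway`.}
#'   \item{`readOrthology`}{columns `protein_a`, `protein_b`.}
#'   \item{`readProteinInfo`}{columns `accession`, `gene`, `modified_residues`
#'     (`;`-separated labels, may be empty), `taxon`.}
#'   \item{`readRegulatoryEdges`}{columns `regulator`, `target_gene`, `mode`,
#'     `source_db`; `mode` is normalised to activator/repressor/unknown and
#'     target symbols to upper case.}
#'   \item{`readDbtfCatalog`}{column `protein` — the DNA-binding
#'     transcription-factor catalog.}
#'   \item{`readExpressionEvidence`}{columns `entity`, `expressed`,
#'     `responsive` (boolean-ish values; yes/true/1 accepted).}
#'   \item{`readLiteratureEvidence`}{columns `entity`,
#'     `responsive_to_other_stimuli`.}
#'   \item{`readNetworkMembership`}{column `member` — the documented network
#'     map members.}
#'   \item{`readDirectStatements`}{columns `subject`, `predicate`, `object` —
#'     pre-formed statements (used for relation-specific annotations that
#'     GAF cannot express).}
#' }
#'
#' @inheritParams readGAF
#' @return A `data.frame` with the documented columns.
#' @name table-readers
NULL

#' @rdname table-readers
#' @export
readIdMapping <- function(stream) {
  readTable(stream, c("source_ns", "source_id", "target"))
}

#' @rdname table-readers
#' @export
readPathways <- function(stream) readTable(stream, c("protein", "pathway"))

#' @rdname table-readers
#' @export
readOrthology <- function(stream) {
  readTable(stream, c("protein_a", "protein_b"))
}

#' @rdname table-readers
#' @export
readProteinInfo <- function(stream) {
  readTable(stream, c("accession", "gene", "modified_residues", "taxon"))
}

#' @rdname table-readers
#' @export
readRegulatoryEdges <- function(stream) {
  df <- readTable(stream, c("regulator", "target_gene", "mode", "source_db"))
  df$mode <- tolower(trimws(df$mode))
  df$mode[!df$mode %in% c("activator", "repressor")] <- "unknown"
  df$target_gene <- toupper(trimws(df$target_gene))
  df
}

#' @rdname table-readers
#' @export
readDbtfCatalog <- function(stream) readTable(stream, "protein")

#' @rdname table-readers
#' @export
readExpressionEvidence <- function(stream) {
  df <- readTable(stream, c("entity", "expressed", "responsive"))
  df$expressed <- asFlag(df$expressed)
  df$responsive <- asFlag(df$responsive)
  df
}

#' @rdname table-readers
#' @export
readLiteratureEvidence <- function(stream) {
  df <- readTable(stream, c("entity", "responsive_to_other_stimuli"))
  df$responsive_to_other_stimuli <- asFlag(df$responsive_to_other_stimuli)
  df
}

#' @rdname table-readers
#' @export
readNetworkMembership <- function(stream) readTable(stream, "member")

#' @rdname table-readers
#' @export
readDirectStatements <- function(stream) {
  readTable(stream, c("subject", "predicate", "object"))
}
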