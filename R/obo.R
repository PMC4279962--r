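#' Parse an OBO 1.2 ontology
#'
#' Reads `[Term]` and `[Typedef]` stanzas. Recognised tags: `id`, `name`,
#' `is_a`, `relationship` (terms) and `id`, `name`, `is_a`, `is_transitive`,
#' `is_reflexive` (typedefs). Each `is_a` or `relationship` line becomes one
#' asserted statement. Unknown tags are ignored; one warning summarises
#' which tags were skipped. Trailing `! comments` are stripped.
#'
#' @param stream A file path, a connection, or a character vector of OBO
#'   lines.
#' @param name Name for the resulting graph (defaults to the `ontology:`
#'   header when present, else `"obo"`).
#' @return A [KnowledgeGraph-class]. Terms whose `relationship` lines use a
#'   relation never declared as a `[Typedef]` raise an error; a stanza with
#'   no `id` raises an error naming the offending line.
#' @examples
#' g <- parseOBO(c("[Term]", "id: GO:0000001", "name: root",
#'                 "[Term]", "id: GO:0000002", "is_a: GO:0000001"))
#' nrow(kgStatements(g))
#' @export
parseOBO <- function(stream, name = NULL) {
  lines <- if (is.character(stream) && length(stream) == 1L &&
               file.exists(stream)) readLines(stream, warn = FALSE)
           else if (inherits(stream, "connection")) readLines(stream,
                                                              warn = FALSE)
           else as.character(stream)
  lines <- sub("\\s+!.*$", "", lines)   # trailing comments
  lines <- sub("\\s+$", "", lines)

  stanzaStart <- grepl("^\\[(Term|Typedef)\\]$", lines)
  headerEnd <- if (any(stanzaStart)) which(stanzaStart)[1] - 1L
               else length(lines)
  if (is.null(name)) {
    ont <- grep("^ontology:", utils::head(lines, headerEnd), value = TRUE)
    name <- if (length(ont)) trimws(sub("^ontology:", "", ont[1])) else "obo"
  }

  terms <- list(); typedefs <- list(); stsubj <- character()
  stpred <- character(); stobj <- character()
  unknownTags <- character()
  kind <- NA_character_; cur <- NULL; curLine <- NA_integer_

  flush <- function() {
    if (is.na(kind)) return()
    if (is.null(cur$id)) {
      stop("OBO stanza starting at line ", curLine, " has no id tag")
    }
    if (kind == "Term") terms[[length(terms) + 1L]] <<- cur
    else typedefs[[length(typedefs) + 1L]] <<- cur
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) {
      flush()
      if (ln %in% c("[Term]", "[Typedef]")) {
        kind <- sub("^\\[(.*)\\]$", "\\1", ln)
        cur <- list(); curLine <- i
      } else {
        kind <- NA_character_; cur <- NULL   # unknown stanza: skip whole
      }
      next
    }
    if (is.na(kind)) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) next
    tag <- m[2]; val <- trimws(m[3])
    if (tag == "id") cur$id <- val
    else if (tag == "name") cur$name <- val
    else if (tag == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (kind == "Term" && tag == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) < 2L) {
        stop("malformed relationship line ", i, ": ", ln)
      }
      cur$rel <- rbind(cur$rel, c(parts[1], parts[2]))
    } else if (kind == "Typedef" && tag == "is_transitive") {
      cur$transitive <- identical(tolower(val), "true")
    } else if (kind == "Typedef" && tag == "is_reflexive") {
      cur$reflexive <- identical(tolower(val), "true")
    } else {
      unknownTags <- c(unknownTags, tag)
    }
  }
  flush()
  if (length(unknownTags)) {
    warning("ignored OBO tags: ", toString(sort(unique(unknownTags))))
  }

  rl <- data.frame(id = "is_a", name = "is_a", transitive = TRUE,
                   reflexive = FALSE, stringsAsFactors = FALSE)
  for (td in typedefs) {
    rl <- rbind(rl, data.frame(
      id = td$id, name = if (is.null(td$name)) td$id else td$name,
      transitive = isTRUE(td$transitive),
      reflexive = isTRUE(td$reflexive), stringsAsFactors = FALSE))
  }
  rl <- rl[!duplicated(rl$id), , drop = FALSE]

  ## typedef-level is_a lines declare superrelations
  sr <- NULL
  for (td in typedefs) {
    for (sup in td$is_a) {
      sr <- rbind(sr, data.frame(relation = td$id, superrelation = sup,
                                 stringsAsFactors = FALSE))
      if (!sup %in% rl$id) {
        rl <- rbind(rl, data.frame(id = sup, name = sup, transitive = FALSE,
                                   reflexive = FALSE, stringsAsFactors = FALSE))
      }
    }
  }

  nid <- vapply(terms, function(t) t$id, character(1))
  nlab <- vapply(terms, function(t) {
    if (is.null(t$name)) t$id else t$name
  }, character(1))
  for (t in terms) {
    for (parent in t$is_a) {
      stsubj <- c(stsubj, t$id); stpred <- c(stpred, "is_a")
      stobj <- c(stobj, parent)
    }
    if (!is.null(t$rel)) {
      for (k in seq_len(nrow(t$rel))) {
        if (!t$rel[k, 1] %in% rl$id) {
          stop("relationship uses undeclared relation '", t$rel[k, 1],
               "' in term ", t$id)
        }
        stsubj <- c(stsubj, t$id); stpred <- c(stpred, t$rel[k, 1])
        stobj <- c(stobj, t$rel[k, 2])
      }
    }
  }

  nodes <- if (length(nid)) data.frame(id = nid, label = nlab,
                                       stringsAsFactors = FALSE) else NULL
  ## parents referenced but not declared as stanzas still become nodes
  extra <- setdiff(stobj, nid)
  if (length(extra)) {
    nodes <- rbind(nodes, data.frame(id = extra, label = extra,
                                     stringsAsFactors = FALSE))
  }
  st <- if (length(stsubj)) {
    data.frame(subject = stsubj, predicate = stpred, object = stobj,
               provenance = "asserted", source = "obo", stringsAsFactors = FALSE)
  } else NULL
  knowledgeGraph(name, nodes = nodes, relations = rl, superRelations = sr,
                 statements = st)
}

#' Serialise a graph to OBO 1.2
#'
#' Writes `[Typedef]` stanzas for every relation type and `[Term]` stanzas
#' for every node, with `is_a:` and `relationship:` lines for the asserted
#' statements. Output is deterministic: stanzas and statement lines are
#' sorted lexicographically by CURIE. Inferred statements are not written
#' (the OBO file is the asserted record; closures are exported as N-Triples).
#'
#' @param graph A [KnowledgeGraph-class].
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly, when `path` is `NULL`) the character
#'   vector of OBO lines.
#' @export
serializeOBO <- function(graph, path = NULL) {
  out <- c("format-version: 1.2", paste0("ontology: ", kgName(graph)), "")
  rl <- kgRelations(graph)
  rl <- rl[rl$id != "is_a", , drop = FALSE]
  rl <- rl[order(rl$id), , drop = FALSE]
  sr <- kgSuperRelations(graph)
  for (i in seq_len(nrow(rl))) {
    out <- c(out, "[Typedef]", paste0("id: ", rl$id[i]),
             paste0("name: ", rl$name[i]))
    sups <- sort(sr$superrelation[sr$relation == rl$id[i]])
    out <- c(out, paste0("is_a: ", sups))
    if (rl$transitive[i]) out <- c(out, "is_transitive: true")
    if (rl$reflexive[i]) out <- c(out, "is_reflexive: true")
    out <- c(out, "")
  }
  nd <- kgNodes(graph); nd <- nd[order(nd$id), , drop = FALSE]
  st <- assertedStatements(graph)
  st <- st[order(st$subject, st$predicate, st$object), , drop = FALSE]
  for (i in seq_len(nrow(nd))) {
    out <- c(out, "[Term]", paste0("id: ", nd$id[i]),
             paste0("name: ", nd$label[i]))
    mine <- st[st$subject == nd$id[i], , drop = FALSE]
    for (k in seq_len(nrow(mine))) {
      out <- c(out,
               if (mine$predicate[k] == "is_a") paste0("is_a: ", mine$object[k])
               else paste0("relationship: ", mine$predicate[k], " ",
                           mine$object[k]))
    }
    out <- c(out, "")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Export a graph as N-Triples
#'
#' One URI per node under a single base IRI, using the triple dialect
#' (`namespace_local_id`). Statement provenance can be used as a filter so
#' that the asserted record and the inference layer can be exported as
#' separate graph files. Output lines are sorted for byte-identical
#' re-runs.
#'
#' @param graph A [KnowledgeGraph-class].
#' @param path Optional file path; when `NULL` the lines are returned.
#' @param base Base IRI (with trailing separator).
#' @param provenance `NULL` for all statements, or `"asserted"` /
#'   `"inferred"`.
#' @return Invisibly (or visibly when `path` is `NULL`) the N-Triples lines.
#' @export
writeNTriples <- function(graph, path = NULL,
                          base = "http://example.org/kb/",
                          provenance = NULL) {
  st <- kgStatements(graph, provenance = provenance)
  uri <- function(x) paste0("<", base, curieToTriple(x), ">")
  lines <- if (nrow(st)) {
    sort(paste(uri(st$subject), paste0("<", base, st$predicate, ">"),
               uri(st$object), "."))
  } else character()
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
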