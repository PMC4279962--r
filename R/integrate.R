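#' Default relation vocabulary
#'
#' The relation types used to populate protein-centric graphs, with the
#' metadata that drives inference. `is_a` and `part_of` are transitive;
#' the three annotation relations (`participates_in`, `has_function`,
#' `located_in`) carry priority over subsumption so annotations propagate
#' across the `is_a` hierarchy; `activates` and `represses` are
#' sub-relations of `regulates`; each annotation relation additionally has a
#' `directly_*` sub-relation for sources that distinguish direct from
#' propagated assignments. One default composition is declared:
#' `part_of` over `part_of` yields `part_of`.
#'
#' @return A list with elements `relations`, `superRelations`,
#'   `compositions` — the three metadata tables accepted by
#'   [knowledgeGraph()].
#' @seealso [readRelationMetadata()] for the TSV serialisation.
#' @export
defaultRelations <- function() {
  relations <- data.frame(
    id = c("is_a", "part_of", "participates_in", "has_function",
           "located_in", "member_of_pathway", "encoded_by",
           "has_modified_residue", "in_taxon", "has_participant",
           "has_interaction_type", "regulates", "activates", "represses",
           "directly_participates_in", "directly_has_function",
           "directly_located_in"),
    transitive = c(TRUE, TRUE, rep(FALSE, 15)),
    reflexive = FALSE,
    priority_over_subsumption = c(FALSE, FALSE, TRUE, TRUE, TRUE,
                                  rep(FALSE, 12)),
    stringsAsFactors = FALSE
  )
  superRelations <- data.frame(
    relation = c("activates", "represses", "directly_participates_in",
                 "directly_has_function", "directly_located_in"),
    superrelation = c("regulates", "regulates", "participates_in",
                      "has_function", "located_in"),
    stringsAsFactors = FALSE
  )
  compositions <- data.frame(
    relation = "part_of", second = "part_of", produces = "part_of",
    stringsAsFactors = FALSE
  )
  list(relations = relations, superRelations = superRelations,
       compositions = compositions)
}

#' Read relation metadata from a TSV config
#'
#' Columns: `id`, `transitive`, `reflexive`, `priority_over_subsumption`
#' (boolean-ish), `superrelations` (`;`-separated relation ids, may be
#' empty) and `compositions` (`;`-separated `second>produces` pairs: a
#' statement `x id y` composed with `y second z` yields `x produces z`).
#' The packaged default is at
#' `system.file("extdata", "relations.tsv", package = "regkb")`.
#'
#' @inheritParams readGAF
#' @return A list shaped like [defaultRelations()].
#' @export
readRelationMetadata <- function(stream) {
  df <- readTable(stream, c("id", "transitive", "reflexive",
                            "priority_over_subsumption", "superrelations",
                            "compositions"))
  sr <- NULL; cp <- NULL
  for (i in seq_len(nrow(df))) {
    sups <- strsplit(df$superrelations[i], ";", fixed = TRUE)[[1]]
    sups <- trimws(sups[nzchar(trimws(sups))])
    if (length(sups)) {
      sr <- rbind(sr, data.frame(relation = df$id[i], superrelation = sups,
                                 stringsAsFactors = FALSE))
    }
    comps <- strsplit(df$compositions[i], ";", fixed = TRUE)[[1]]
    comps <- trimws(comps[nzchar(trimws(comps))])
    for (cmp in comps) {
      pair <- trimws(strsplit(cmp, ">", fixed = TRUE)[[1]])
      if (length(pair) != 2L) {
        stop("malformed composition entry '", cmp, "' for relation ",
             df$id[i])
      }
      cp <- rbind(cp, data.frame(relation = df$id[i], second = pair[1],
                                 produces = pair[2], stringsAsFactors = FALSE))
    }
  }
  list(
    relations = data.frame(
      id = df$id, transitive = asFlag(df$transitive),
      reflexive = asFlag(df$reflexive),
      priority_over_subsumption = asFlag(df$priority_over_subsumption),
      stringsAsFactors = FALSE),
    superRelations = normaliseSuperRelations(sr),
    compositions = normaliseCompositions(cp)
  )
}

#' Build an identifier mapping
#'
#' The mapping is the identifier-normalisation contract: a total function on
#' its declared `(source namespace, source id)` keys returning the canonical
#' protein CURIE; anything outside the declared keys maps to absent (`NA`),
#' never to a fabricated identifier.
#'
#' @param table `data.frame` with columns `source_ns`, `source_id`, `target`
#'   (as returned by [readIdMapping()]).
#' @return A named character vector: names are source CURIEs
#'   (`namespace:local_id`), values the canonical CURIEs.
#' @export
idMapping <- function(table) {
  stopifnot(all(c("source_ns", "source_id", "target") %in% names(table)))
  if (!nrow(table)) return(stats::setNames(character(), character()))
  keys <- curie(table$source_ns, table$source_id)
  stats::setNames(as.character(table$target), keys)
}

#' @rdname idMapping
#' @param x Character vector of source CURIEs to look up.
#' @param mapping A mapping from `idMapping()`.
#' @return `mapIds()` returns the canonical CURIEs, `NA` where unmapped.
#' @export
mapIds <- function(x, mapping) {
  out <- unname(mapping[x])
  out
}

#' Apply the identifier-mapping filter
#'
#' Rewrites the identifier columns of a record table to canonical CURIEs and
#' drops every row containing at least one unmappable identifier — dropping
#' is the contract; no identifier is ever fabricated.
#'
#' @param records A record `data.frame` (annotations, interactions,
#'   pathway/orthology rows, ...).
#' @param mapping A mapping from [idMapping()].
#' @param columns Columns to map. The default picks the protein-identifier
#'   columns present in `records` (`protein`, `participant_a`,
#'   `participant_b`, `protein_a`, `protein_b`, `accession`, `regulator`).
#' @return A list with `kept` (mapped rows) and `dropped` (row count).
#' @export
applyIdMapping <- function(records, mapping, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(names(records),
                         c("protein", "participant_a", "participant_b",
                           "protein_a", "protein_b", "accession",
                           "regulator"))
  }
  if (!nrow(records) || !length(columns)) {
    return(list(kept = records, dropped = 0L))
  }
  ok <- rep(TRUE, nrow(records))
  for (col in columns) {
    mapped <- mapIds(records[[col]], mapping)
    ok <- ok & !is.na(mapped)
    records[[col]] <- mapped
  }
  kept <- records[ok, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, dropped = sum(!ok))
}

#' Select core proteins by seed-ontology annotation
#'
#' Core proteins are those carrying at least one Biological Process (aspect
#' `P`) annotation whose term is present in the seed ontology. They anchor
#' the association-based extension: a narrower seed always yields a subset
#' of the core of a wider seed.
#'
#' @param annotations Annotation `data.frame` (see [readGAF()]).
#' @param seed A [KnowledgeGraph-class] holding the seed ontology terms.
#' @return Sorted character vector of protein CURIEs.
#' @export
selectCoreProteins <- function(annotations, seed) {
  if (!nrow(annotations)) return(character())
  hit <- annotations$aspect == "P" &
    annotations$go_term %in% kgNodes(seed)$id
  sort(unique(annotations$protein[hit]))
}

#' Extend a protein set by association
#'
#' One expansion round: the core plus every protein that shares an
#' interaction, a pathway or an orthology pair with a core protein. The
#' round is applied exactly once — partners of partners are not pulled in —
#' so growth is bounded and reproducible. Set `rounds` to iterate if a wider
#' neighbourhood is wanted.
#'
#' @param core Character vector of core protein CURIEs.
#' @param interactions Interaction `data.frame` (see [readMITAB()]) or
#'   `NULL`.
#' @param pathways Pathway-membership `data.frame` or `NULL`.
#' @param orthology Orthology-pair `data.frame` or `NULL`.
#' @param rounds Number of expansion rounds (default 1).
#' @return Sorted character vector of protein CURIEs.
#' @export
extendByAssociation <- function(core, interactions = NULL, pathways = NULL,
                                orthology = NULL, rounds = 1L) {
  result <- unique(core)
  for (r in seq_len(rounds)) {
    new <- character()
    if (!is.null(interactions) && nrow(interactions)) {
      hitA <- interactions$participant_a %in% result
      hitB <- interactions$participant_b %in% result
      new <- c(new, interactions$participant_b[hitA],
               interactions$participant_a[hitB])
    }
    if (!is.null(pathways) && nrow(pathways)) {
      corePw <- unique(pathways$pathway[pathways$protein %in% result])
      new <- c(new, pathways$protein[pathways$pathway %in% corePw])
    }
    if (!is.null(orthology) && nrow(orthology)) {
      hitA <- orthology$protein_a %in% result
      hitB <- orthology$protein_b %in% result
      new <- c(new, orthology$protein_b[hitA], orthology$protein_a[hitB])
    }
    before <- length(result)
    result <- unique(c(result, new))
    if (length(result) == before) break
  }
  sort(result)
}

#' Populate a seed ontology with protein-centric data
#'
#' Adds the selected proteins and their data-facing statements to the seed
#' graph:
#' * annotations — `participates_in` (aspect P), `has_function` (F),
#'   `located_in` (C);
#' * interactions — one reified interaction node per record, with two
#'   `has_participant` statements and one `has_interaction_type` statement
#'   (only interactions whose participants are both in `proteins` are
#'   integrated);
#' * pathway memberships — `member_of_pathway`, creating pathway nodes;
#' * protein info — `encoded_by` gene statements (gene nodes are created
#'   only when the info table supplies one), `has_modified_residue`
#'   statements with `SSB:` residue nodes (spaces become underscores), and
#'   `in_taxon` statements;
#' * regulatory edges — `activates`, `represses` or `regulates` by mode,
#'   from the regulator protein to the target gene. Symbolic targets (no
#'   mapping to a gene CURIE) become `SYMBOL:` nodes of category gene.
#'
#' All identifiers are expected to be canonical (see [applyIdMapping()]).
#' Ontology terms referenced by annotations must exist in the seed; with
#' `skipUnknownTerms = TRUE` such records are dropped instead of raising an
#' error.
#'
#' @param seed A [KnowledgeGraph-class] (the seed ontology).
#' @param proteins Character vector of protein CURIEs to integrate.
#' @param annotations,interactions,pathways,infos,edges Record tables from
#'   the corresponding readers, or `NULL`.
#' @param directStatements Optional `data.frame` of pre-formed
#'   `subject`/`predicate`/`object` statements (e.g. relation-specific
#'   annotations), added as asserted.
#' @param geneMapping Optional [idMapping()] vector from target-gene symbols
#'   (`SYMBOL:` CURIEs) to gene CURIEs; unmapped symbols stay symbolic.
#' @param skipUnknownTerms Drop annotation records whose term is not a seed
#'   node instead of erroring.
#' @param name Name for the populated graph.
#' @return A [KnowledgeGraph-class].
#' @export
populateGraph <- function(seed, proteins, annotations = NULL,
                          interactions = NULL, pathways = NULL,
                          infos = NULL, edges = NULL,
                          directStatements = NULL, geneMapping = NULL,
                          skipUnknownTerms = FALSE,
                          name = kgName(seed)) {
  ## relations the seed already declares keep the seed's metadata; the
  ## default table fills in the rest (conflicting declarations error via
  ## the mergeGraphs contract)
  rels <- defaultRelations()
  seedRel <- kgRelations(seed)
  defRel <- normaliseRelations(rels$relations)
  relTable <- rbind(seedRel,
                    defRel[!defRel$id %in% seedRel$id, , drop = FALSE])
  g <- mergeGraphs(list(
    seed,
    knowledgeGraph("relations", relations = relTable,
                   superRelations = rels$superRelations,
                   compositions = rels$compositions)
  ), name = name)

  nodes <- g@nodes
  st <- g@statements
  addNode <- function(id, label = id, category = termCategory(id)) {
    add <- data.frame(id = id, label = label, category = category,
                      stringsAsFactors = FALSE)
    add <- add[!duplicated(add$id), , drop = FALSE]
    add <- add[!add$id %in% nodes$id, , drop = FALSE]
    if (nrow(add)) nodes <<- rbind(nodes, add)
  }
  addSt <- function(subject, predicate, object, source) {
    if (!length(subject)) return()
    st <<- rbind(st, data.frame(subject = subject, predicate = predicate,
                                object = object, provenance = "asserted",
                                source = source, stringsAsFactors = FALSE))
  }

  proteins <- sort(unique(proteins))
  addNode(proteins)

  if (!is.null(annotations) && nrow(annotations)) {
    ann <- annotations[annotations$protein %in% proteins, , drop = FALSE]
    known <- ann$go_term %in% nodes$id
    if (!all(known)) {
      if (skipUnknownTerms) {
        ann <- ann[known, , drop = FALSE]
      } else {
        stop("annotation term(s) not in seed ontology: ",
             toString(utils::head(unique(ann$go_term[!known]), 5)))
      }
    }
    pred <- c(P = "participates_in", F = "has_function", C = "located_in")
    addSt(ann$protein, unname(pred[ann$aspect]), ann$go_term, "gaf")
  }

  if (!is.null(interactions) && nrow(interactions)) {
    ia <- interactions[interactions$participant_a %in% proteins &
                       interactions$participant_b %in% proteins, ,
                       drop = FALSE]
    if (nrow(ia)) {
      addNode(ia$interaction_id)
      addNode(ia$interaction_type)
      addSt(ia$interaction_id, "has_participant", ia$participant_a, "mitab")
      addSt(ia$interaction_id, "has_participant", ia$participant_b, "mitab")
      addSt(ia$interaction_id, "has_interaction_type", ia$interaction_type,
            "mitab")
    }
  }

  if (!is.null(pathways) && nrow(pathways)) {
    pw <- pathways[pathways$protein %in% proteins, , drop = FALSE]
    if (nrow(pw)) {
      addNode(pw$pathway)
      addSt(pw$protein, "member_of_pathway", pw$pathway, "pathways")
    }
  }

  if (!is.null(infos) && nrow(infos)) {
    inf <- infos[infos$accession %in% proteins, , drop = FALSE]
    hasGene <- !is.na(inf$gene) & nzchar(trimws(inf$gene))
    if (any(hasGene)) {
      addNode(inf$gene[hasGene])
      addSt(inf$accession[hasGene], "encoded_by", inf$gene[hasGene],
            "protein-info")
    }
    for (i in seq_len(nrow(inf))) {
      res <- strsplit(inf$modified_residues[i], ";", fixed = TRUE)[[1]]
      res <- trimws(res[nzchar(trimws(res))])
      if (length(res)) {
        ids <- curie("SSB", res)
        addNode(ids, label = res)
        addSt(rep(inf$accession[i], length(ids)), "has_modified_residue",
              ids, "protein-info")
      }
    }
    hasTaxon <- !is.na(inf$taxon) & nzchar(trimws(inf$taxon))
    if (any(hasTaxon)) {
      addNode(inf$taxon[hasTaxon])
      addSt(inf$accession[hasTaxon], "in_taxon", inf$taxon[hasTaxon],
            "protein-info")
    }
  }

  if (!is.null(edges) && nrow(edges)) {
    targets <- edges$target_gene
    symbolic <- !grepl(":", targets)
    targets[symbolic] <- curie("SYMBOL", toupper(targets[symbolic]))
    if (!is.null(geneMapping)) {
      mapped <- mapIds(targets, geneMapping)
      targets[!is.na(mapped)] <- mapped[!is.na(mapped)]
    }
    addNode(edges$regulator)
    isSym <- startsWith(targets, "SYMBOL:")
    addNode(targets[isSym], label = curieLocal(targets[isSym]),
            category = "gene")
    addNode(targets[!isSym])
    pred <- c(activator = "activates", repressor = "represses",
              unknown = "regulates")
    addSt(edges$regulator, unname(pred[edges$mode]), targets,
          paste0("regulatory:", edges$source_db))
  }

  if (!is.null(directStatements) && nrow(directStatements)) {
    ds <- directStatements
    unknown <- setdiff(unique(c(ds$subject, ds$object)), nodes$id)
    if (length(unknown)) {
      stop("direct statement references unknown node(s): ",
           toString(utils::head(unknown, 5)))
    }
    addSt(ds$subject, ds$predicate, ds$object, "direct")
  }

  rownames(nodes) <- NULL
  g@nodes <- nodes
  g@statements <- dedupStatements(st)
  validObject(g)
  g
}
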