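## Stage drivers behind the command-line pipeline (inst/scripts/kgpipeline.R).
## Each stage validates its inputs up front, assembles results in memory and
## only then writes, so failures never leave partial output behind.

packagedRelationsPath <- function() {
  system.file("extdata", "relations.tsv", package = "regkb",
              mustWork = TRUE)
}

## Replace inference metadata for the relation ids a config declares,
## keeping any graph-local relations the config does not mention.
overlayRelationMetadata <- function(graph, meta) {
  rl <- kgRelations(graph)
  metaRel <- normaliseRelations(meta$relations)
  keep <- rl[!rl$id %in% metaRel$id, , drop = FALSE]
  newRel <- normaliseRelations(rbind(keep, metaRel))
  declared <- newRel$id
  st <- graph@statements
  usedPred <- unique(st$predicate)
  missing <- setdiff(usedPred, declared)
  if (length(missing)) {
    stop("relation metadata does not declare: ", toString(missing))
  }
  sr <- meta$superRelations
  sr <- sr[sr$relation %in% declared & sr$superrelation %in% declared, ,
           drop = FALSE]
  cp <- meta$compositions
  cp <- cp[cp$relation %in% declared & cp$second %in% declared &
             cp$produces %in% declared, , drop = FALSE]
  graph@relations <- newRel
  graph@superRelations <- normaliseSuperRelations(sr)
  graph@compositions <- normaliseCompositions(cp)
  validObject(graph)
  graph
}

writeManifest <- function(outDir, stage, fields) {
  manifest <- c(list(stage = stage, written = format(Sys.time(),
                                                     "%Y-%m-%dT%H:%M:%S")),
                fields)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

requireFiles <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", toString(missing))
  }
  invisible(paths)
}

#' Pipeline stage drivers
#'
#' Five stages mirroring the knowledge-base workflow, each runnable from R
#' or through the `inst/scripts/kgpipeline.R` command-line wrapper
#' (subcommands `simulate`, `build`, `close`, `query`, `prioritize`).
#' Outputs are deterministic given identical inputs and seed; every stage
#' writes a `manifest.json` with the counts it produced.
#'
#' \describe{
#'   \item{`runSimulate`}{generates a synthetic fixture bundle (see
#'     [generateKB()] / [writeKBFiles()]).}
#'   \item{`runBuild`}{reads a bundle (`ontology.obo`, `annotations.gaf`,
#'     `interactions.mitab`, `pathways.tsv`, `orthology.tsv`,
#'     `protein_info.tsv`, `regulatory_edges.tsv`, optional
#'     `statements.tsv`), selects core proteins by seed-ontology
#'     annotation, extends them by association and populates the graph;
#'     with `roots` given, one nested graph is built per sub-domain root.
#'     Each graph is written back as OBO.}
#'   \item{`runClose`}{parses a built OBO graph, overlays the relation
#'     metadata config and computes the total closure, exporting asserted
#'     and inferred N-Triples plus closure statistics.}
#'   \item{`runQuery`}{evaluates a built-in template against the closure
#'     and writes `candidates.tsv` (protein, clauses, provenance class)
#'     with the provenance partition in the manifest.}
#'   \item{`runPrioritize`}{computes shared target genes between the novel
#'     and core regulator sets and assesses them against expression
#'     evidence; defaults to the packaged worked example
#'     ([table2Fixture()]). Optionally classifies a candidate list against
#'     a network membership map.}
#' }
#'
#' @param outDir Output directory (created if needed).
#' @param config A [synthConfig()].
#' @return Each driver invisibly returns its main in-memory result (paths,
#'   graphs, a [ClosureResult-class], or result tables).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
runSimulate <- function(outDir, config = synthConfig()) {
  kb <- generateKB(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- writeKBFiles(kb, outDir)
  writeManifest(outDir, "simulate", list(
    seed = config$seed, planting_mode = config$plantingMode,
    nodes = nrow(kgNodes(kb$graph)),
    statements = nrow(kgStatements(kb$graph)),
    planted = nrow(kb$ledger)))
  message("simulate: wrote ", length(paths), " files to ", outDir)
  invisible(kb)
}

#' @rdname pipeline
#' @param inputDir Directory holding the input bundle.
#' @param roots Optional named character vector of sub-domain root CURIEs;
#'   one nested graph is built per entry.
#' @param relationsPath Relation metadata TSV (defaults to the packaged
#'   config).
#' @param idMappingPath Optional identifier-mapping TSV; when given, all
#'   record tables pass the mapping filter first.
#' @export
runBuild <- function(inputDir, outDir, roots = NULL,
                     relationsPath = NULL, idMappingPath = NULL) {
  files <- c(ontology = "ontology.obo", annotations = "annotations.gaf",
             interactions = "interactions.mitab", pathways = "pathways.tsv",
             orthology = "orthology.tsv", protein_info = "protein_info.tsv",
             regulatory_edges = "regulatory_edges.tsv")
  paths <- stats::setNames(file.path(inputDir, files), names(files))
  requireFiles(paths)
  stmtPath <- file.path(inputDir, "statements.tsv")
  if (is.null(relationsPath)) relationsPath <- packagedRelationsPath()
  requireFiles(relationsPath)

  ont <- parseOBO(paths["ontology"])
  ann <- readGAF(paths["annotations"])
  ia <- readMITAB(paths["interactions"])
  pwt <- readPathways(paths["pathways"])
  orth <- readOrthology(paths["orthology"])
  infos <- readProteinInfo(paths["protein_info"])
  edges <- readRegulatoryEdges(paths["regulatory_edges"])
  direct <- if (file.exists(stmtPath)) readDirectStatements(stmtPath)
            else NULL
  dropped <- 0L
  if (!is.null(idMappingPath)) {
    mapping <- idMapping(readIdMapping(idMappingPath))
    for (nm in c("ann", "ia", "orth", "infos", "edges")) {
      res <- applyIdMapping(get(nm), mapping)
      assign(nm, res$kept)
      dropped <- dropped + res$dropped
    }
    res <- applyIdMapping(pwt, mapping, columns = "protein")
    pwt <- res$kept; dropped <- dropped + res$dropped
  }
  meta <- readRelationMetadata(relationsPath)
  ont <- overlayRelationMetadata(ont, meta)

  buildOne <- function(seed, name) {
    core <- selectCoreProteins(ann, seed)
    proteins <- extendByAssociation(core, ia, pwt, orth)
    proteins <- unique(c(proteins, edges$regulator,
                         ia$participant_a, ia$participant_b))
    if (!is.null(direct)) {
      subj <- unique(direct$subject)
      proteins <- unique(c(proteins,
                           subj[termCategory(subj) == "protein"]))
    }
    populateGraph(seed, proteins, annotations = ann, interactions = ia,
                  pathways = pwt, infos = infos, edges = edges,
                  directStatements = direct, skipUnknownTerms = TRUE,
                  name = name)
  }
  graphs <- if (is.null(roots)) {
    list(kb = buildOne(ont, "kb"))
  } else {
    out <- list()
    for (nm in names(roots)) {
      sub <- extractSubdomain(ont, roots[[nm]], name = nm)
      out[[nm]] <- buildOne(sub, nm)
    }
    out
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(graphs)) {
    serializeOBO(graphs[[nm]], file.path(outDir, paste0(nm, ".obo")))
  }
  writeManifest(outDir, "build", list(
    graphs = lapply(graphs, function(g) {
      list(nodes = nrow(kgNodes(g)), statements = nrow(kgStatements(g)))
    }),
    dropped_by_id_mapping = dropped))
  message("build: ", length(graphs), " graph(s) written to ", outDir)
  invisible(graphs)
}

loadBuiltGraph <- function(oboPath, relationsPath = NULL) {
  requireFiles(oboPath)
  if (is.null(relationsPath)) relationsPath <- packagedRelationsPath()
  requireFiles(relationsPath)
  g <- parseOBO(oboPath)
  overlayRelationMetadata(g, readRelationMetadata(relationsPath))
}

#' @rdname pipeline
#' @param oboPath A built graph in OBO form (from `runBuild`).
#' @param rules Rule kinds to chain (default all of [ruleKinds()]).
#' @param base Base IRI for N-Triples export.
#' @export
runClose <- function(oboPath, outDir, relationsPath = NULL,
                     rules = ruleKinds(), base = "http://example.org/kb/") {
  g <- loadBuiltGraph(oboPath, relationsPath)
  res <- computeClosure(g, rules = rules)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  nm <- kgName(res$graph)
  writeNTriples(res$graph, file.path(outDir, paste0(nm, ".asserted.nt")),
                base = base, provenance = "asserted")
  writeNTriples(res$graph, file.path(outDir, paste0(nm, ".inferred.nt")),
                base = base, provenance = "inferred")
  writeManifest(outDir, "close", list(
    graph = nm, asserted = res$assertedCount, inferred = res$inferredCount,
    fold_increase = res$foldIncrease,
    per_rule = as.list(res$perRuleCounts)))
  message("close: ", nm, " fold increase ",
          format(res$foldIncrease, digits = 4))
  invisible(res)
}

#' @rdname pipeline
#' @param template Built-in template name (`"Q1"`..`"Q5"`).
#' @param targetIds Role overrides for [builtinTemplates()].
#' @export
runQuery <- function(oboPath, outDir, template = "Q1",
                     targetIds = character(), relationsPath = NULL) {
  g <- loadBuiltGraph(oboPath, relationsPath)
  tmpl <- builtinTemplates(targetIds)[[match.arg(template,
                                                 paste0("Q", 1:5))]]
  res <- computeClosure(g)
  hits <- evaluateTemplate(tmpl, res$graph)
  part <- provenancePartition(tmpl, g, res$graph)
  out <- merge(hits, part$classes, by = "protein", all.x = TRUE)
  out <- out[order(out$protein), , drop = FALSE]
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeTsv(out, file.path(outDir, "candidates.tsv"))
  writeManifest(outDir, "query", list(
    template = tmpl$name, hits = nrow(out),
    partition = as.list(part$counts)))
  message("query ", tmpl$name, ": ", nrow(out), " candidate(s), ",
          part$counts[["inferred_only"]], " inferred-only")
  invisible(list(candidates = out, partition = part))
}

#' @rdname pipeline
#' @param edgesPath Regulatory-edge TSV; `NULL` uses the packaged worked
#'   example.
#' @param novel,core Regulator identifier vectors (required with
#'   `edgesPath`).
#' @param targetExpressionPath,regulatorExpressionPath Expression-evidence
#'   TSVs (`NULL` uses the packaged worked example).
#' @param candidates Optional candidate vector to classify.
#' @param membershipPath,literaturePath Evidence TSVs for candidate
#'   classification.
#' @export
runPrioritize <- function(outDir, edgesPath = NULL, novel = NULL,
                          core = NULL, targetExpressionPath = NULL,
                          regulatorExpressionPath = NULL,
                          candidates = NULL, membershipPath = NULL,
                          literaturePath = NULL) {
  if (is.null(edgesPath)) {
    fx <- table2Fixture()
    edges <- fx$edges; novel <- fx$novel; core <- fx$core
    targetExpr <- fx$targetExpression
    regExpr <- fx$regulatorExpression
  } else {
    requireFiles(edgesPath)
    edges <- readRegulatoryEdges(edgesPath)
    if (is.null(novel) || is.null(core)) {
      stop("novel and core regulator sets are required with edgesPath")
    }
    targetExpr <- if (!is.null(targetExpressionPath)) {
      readExpressionEvidence(requireFiles(targetExpressionPath))
    } else NULL
    regExpr <- if (!is.null(regulatorExpressionPath)) {
      readExpressionEvidence(requireFiles(regulatorExpressionPath))
    } else NULL
  }
  rows <- sharedTargets(novel, core, edges)
  assessed <- assessTargetGenes(rows, targetExpr, regExpr)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeTsv(assessed, file.path(outDir, "target_assessment.tsv"))
  fields <- list(
    shared_target_rows = nrow(assessed),
    unique_target_genes = length(unique(assessed$target_gene)),
    candidate_genes = length(unique(
      assessed$target_gene[assessed$candidate])),
    dual_supported_genes = length(unique(
      assessed$target_gene[assessed$dual_supported])))
  cls <- NULL
  if (!is.null(candidates)) {
    membership <- if (!is.null(membershipPath)) {
      readNetworkMembership(requireFiles(membershipPath))
    } else character()
    literature <- if (!is.null(literaturePath)) {
      readLiteratureEvidence(requireFiles(literaturePath))
    } else NULL
    cls <- classifyCandidates(candidates, membership, targetExpr,
                              literature)
    writeTsv(cls, file.path(outDir, "classification.tsv"))
    fields$classified <- as.list(table(cls$category))
  }
  writeManifest(outDir, "prioritize", fields)
  message("prioritize: ", fields$shared_target_rows, " shared-target rows, ",
          fields$candidate_genes, " candidate gene(s), ",
          fields$dual_supported_genes, " dual-supported")
  invisible(list(assessment = assessed, classification = cls))
}
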