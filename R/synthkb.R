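#' Synthetic knowledge-base configuration
#'
#' Parameters of the seeded generator. Defaults describe a small but
#' structurally complete knowledge base: a 60-term ontology DAG, 40
#' background proteins with 1–3 annotations each, 30 typed interactions, 5
#' pathways, 25 regulatory edges and 5 planted regulators satisfying the Q1
#' template. `pInferredOnly` is the probability that a planted regulator is
#' constructed to satisfy its template only after closure (its term-clause
#' statements are asserted through `directly_*` sub-relations, so only the
#' superrelation rule exposes them to the template).
#'
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @param nTerms Number of synthetic ontology terms (`SYN:` namespace).
#' @param nProteins Number of background proteins.
#' @param dagBranching Mean number of parents per non-root term.
#' @param nInteractions,nPathways,nRegulatoryEdges Background record
#'   counts.
#' @param nPlantedRegulators Number of planted template-satisfying
#'   regulators.
#' @param plantingMode Which built-in template the plants satisfy
#'   (`"Q1"`..`"Q5"`).
#' @param pInferredOnly Fraction (probability) of plants that are
#'   inferred-only.
#' @return A `SynthConfig` (S3 list).
#' @export
synthConfig <- function(seed = 1L, nTerms = 60L, nProteins = 40L,
                        dagBranching = 1.5, nInteractions = 30L,
                        nPathways = 5L, nRegulatoryEdges = 25L,
                        nPlantedRegulators = 5L, plantingMode = "Q1",
                        pInferredOnly = 0) {
  plantingMode <- match.arg(plantingMode, paste0("Q", 1:5))
  stopifnot(nTerms >= 2L, nProteins >= 0L, nInteractions >= 0L,
            nPathways >= 0L, nRegulatoryEdges >= 0L,
            nPlantedRegulators >= 0L,
            pInferredOnly >= 0, pInferredOnly <= 1)
  structure(list(seed = as.integer(seed), nTerms = as.integer(nTerms),
                 nProteins = as.integer(nProteins),
                 dagBranching = dagBranching,
                 nInteractions = as.integer(nInteractions),
                 nPathways = as.integer(nPathways),
                 nRegulatoryEdges = as.integer(nRegulatoryEdges),
                 nPlantedRegulators = as.integer(nPlantedRegulators),
                 plantingMode = plantingMode,
                 pInferredOnly = pInferredOnly),
            class = "SynthConfig")
}

synId <- function(i) sprintf("SYN:%07d", i)

#' Generate a synthetic knowledge base with planted ground truth
#'
#' Builds a complete, seeded fixture world:
#' * a single-rooted `is_a` DAG of `SYN:` terms (each new term picks its
#'   parents uniformly from the existing terms), linked under the ULO
#'   'Biological Process' anchor;
#' * the real query-term anchors (GO/MI/KEGG CURIEs used by the built-in
#'   templates) injected as leaves so [builtinTemplates()] run unmodified —
#'   background records never touch them, which is what makes planted
#'   recall and precision exactly measurable;
#' * background proteins with GAF annotations to `SYN:` terms, typed
#'   interactions among themselves, pathway memberships, orthology pairs,
#'   protein/gene info and regulatory edges;
#' * `nPlantedRegulators` planted proteins constructed to satisfy the
#'   chosen template, cycling over its clause paths. Plants drawn as
#'   inferred-only assert their term clauses via `directly_*`
#'   sub-relations (emitted as a direct-statements table, since GAF cannot
#'   carry a predicate) and therefore match only on the closure.
#'
#' The graph is assembled through the package's own readers and
#' [populateGraph()], so every emitted record is exercised end-to-end.
#'
#' @param config A [synthConfig()].
#' @return A list: `graph` (the populated [KnowledgeGraph-class]),
#'   `seedGraph` (ontology before protein population), `records` (the
#'   generated tables: `annotations`, `interactions`, `pathways`,
#'   `orthology`, `infos`, `edges`, `directStatements`), `ledger`
#'   (`data.frame` of `protein`, `template`, `inferred_only` — exact ground
#'   truth), and `config`.
#' @export
generateKB <- function(config = synthConfig()) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed)

  ## --- ontology DAG -------------------------------------------------------
  nTerms <- config$nTerms
  termIds <- synId(seq_len(nTerms))
  parents <- character(0); children <- character(0)
  for (i in 2:nTerms) {
    k <- max(1L, min(i - 1L, stats::rpois(1, config$dagBranching - 1) + 1L))
    ps <- sample(termIds[seq_len(i - 1L)], k)
    parents <- c(parents, ps)
    children <- c(children, rep(termIds[i], length(ps)))
  }

  anchorTerms <- c("GO:0032793", "GO:0008140", "GO:0051091", "GO:0032792",
                   "GO:0043433", "GO:0004402", "GO:0004407", "GO:0051090",
                   "GO:0032088", "GO:0000151", "GO:0043130")
  anchorParents <- sample(termIds, length(anchorTerms), replace = TRUE)
  miTerms <- c("MI:0001", "MI:0407", "MI:0914", "MI:0220")

  ont <- knowledgeGraph(
    "synthetic-ontology",
    nodes = data.frame(id = c(termIds, anchorTerms, miTerms)),
    relations = data.frame(id = "is_a", transitive = TRUE),
    statements = data.frame(
      subject = c(children, anchorTerms, miTerms[-1]),
      predicate = "is_a",
      object = c(parents, anchorParents, rep("MI:0001", 3)),
      source = "synth"))
  seedGraph <- linkToULO(assembleULO(), ont, termIds[1], "ULO:0000010",
                         name = "synth-kb")

  ## --- background entities ------------------------------------------------
  prot <- if (config$nProteins)
    sprintf("UniProtKB:SYNP%04d", seq_len(config$nProteins)) else character()
  creb1 <- "UniProtKB:P16220"; tcf7l2 <- "UniProtKB:Q9NQB0"
  nPlants <- config$nPlantedRegulators
  plants <- if (nPlants) sprintf("UniProtKB:PLNT%04d", seq_len(nPlants))
            else character()

  ann <- NULL
  if (length(prot)) {
    for (p in prot) {
      k <- sample(1:3, 1)
      terms <- sample(termIds, k, replace = TRUE)
      aspects <- sample(c("P", "P", "F", "C"), k, replace = TRUE)
      ann <- rbind(ann, data.frame(protein = p, go_term = terms,
                                   aspect = aspects, evidence_code = "IEA",
                                   taxon = "NCBITaxon:9606",
                                   stringsAsFactors = FALSE))
    }
  }

  ia <- NULL
  if (config$nInteractions && length(prot) >= 2L) {
    for (i in seq_len(config$nInteractions)) {
      pr <- sample(prot, 2)
      ia <- rbind(ia, data.frame(
        interaction_id = sprintf("intact:SYN-%04d", i),
        participant_a = pr[1], participant_b = pr[2],
        interaction_type = sample(c("MI:0407", "MI:0914"), 1),
        stringsAsFactors = FALSE))
    }
  }

  pwIds <- if (config$nPathways)
    sprintf("KEGG:syn%05d", seq_len(config$nPathways)) else character()
  pw <- NULL
  if (length(pwIds) && length(prot)) {
    member <- sample(prot, min(length(prot), config$nPathways * 4L),
                     replace = FALSE)
    pw <- data.frame(protein = member,
                     pathway = sample(pwIds, length(member), replace = TRUE),
                     stringsAsFactors = FALSE)
  }

  orth <- NULL
  if (length(prot) >= 4L) {
    nOrth <- max(1L, length(prot) %/% 5L)
    for (i in seq_len(nOrth)) {
      pr <- sample(prot, 2)
      orth <- rbind(orth, data.frame(protein_a = pr[1], protein_b = pr[2],
                                     stringsAsFactors = FALSE))
    }
  }

  infos <- NULL
  if (length(prot)) {
    withGene <- sort(sample(prot, max(0L, length(prot) %/% 2L)))
    infos <- data.frame(
      accession = prot,
      gene = ifelse(prot %in% withGene,
                    sprintf("NCBIGene:9%05d", seq_along(prot)), ""),
      modified_residues = ifelse(seq_along(prot) %% 7L == 0L,
                                 "phospho serine 133", ""),
      taxon = "NCBITaxon:9606", stringsAsFactors = FALSE)
  }

  edges <- NULL
  if (config$nRegulatoryEdges && length(prot)) {
    regs <- sample(prot, min(length(prot), 8L))
    genes <- sprintf("SYNG%02d", 1:12)
    for (i in seq_len(config$nRegulatoryEdges)) {
      edges <- rbind(edges, data.frame(
        regulator = sample(regs, 1), target_gene = sample(genes, 1),
        mode = sample(c("activator", "repressor", "unknown"), 1),
        source_db = sample(c("TFactS", "PAZAR", "HTRI"), 1),
        stringsAsFactors = FALSE))
    }
    edges <- unique(edges)
  }

  ## --- plants -------------------------------------------------------------
  ledger <- data.frame(protein = character(), template = character(),
                       inferred_only = logical(), stringsAsFactors = FALSE)
  direct <- NULL
  nextIa <- config$nInteractions + 1L
  plantIa <- function(a, b, type) {
    row <- data.frame(interaction_id = sprintf("intact:SYN-%04d", nextIa),
                      participant_a = a, participant_b = b,
                      interaction_type = type, stringsAsFactors = FALSE)
    nextIa <<- nextIa + 1L
    ia <<- rbind(ia, row)
  }
  plantAnn <- function(p, term, aspect, inferredOnly) {
    if (inferredOnly) {
      pred <- c(P = "directly_participates_in", F = "directly_has_function",
                C = "directly_located_in")[[aspect]]
      direct <<- rbind(direct, data.frame(subject = p, predicate = pred,
                                          object = term,
                                          stringsAsFactors = FALSE))
    } else {
      ann <<- rbind(ann, data.frame(protein = p, go_term = term,
                                    aspect = aspect, evidence_code = "IEA",
                                    taxon = "NCBITaxon:9606",
                                    stringsAsFactors = FALSE))
    }
  }

  if (nPlants) {
    inferredOnly <- stats::runif(nPlants) < config$pInferredOnly
    mode <- config$plantingMode
    for (i in seq_len(nPlants)) {
      p <- plants[i]; io <- inferredOnly[i]
      if (mode == "Q1") {
        ## cycle clause paths A, D, B+assoc, C (C only for asserted plants:
        ## it is interaction-only, which the inferred-only route cannot
        ## express through a sub-relation annotation)
        paths <- if (io) c("A", "D", "B") else c("A", "D", "B", "C")
        path <- paths[(i - 1L) %% length(paths) + 1L]
        switch(path,
          A = plantAnn(p, "GO:0032793", "P", io),
          D = plantAnn(p, "GO:0008140", "F", io),
          B = { plantAnn(p, "GO:0051091", "P", io)
                plantIa(p, creb1, "MI:0914") },
          C = plantIa(p, creb1, "MI:0407"))
      } else if (mode == "Q2") {
        term <- c("GO:0032792", "GO:0043433")[(i - 1L) %% 2L + 1L]
        plantAnn(p, term, "P", io)
      } else if (mode == "Q3") {
        fn <- c("GO:0004402", "GO:0004407")[(i - 1L) %% 2L + 1L]
        plantAnn(p, fn, "F", FALSE)
        plantAnn(p, "GO:0051090", "P", io)
        plantIa(p, creb1, "MI:0914")
      } else if (mode == "Q4") {
        plantAnn(p, "GO:0032088", "P", io)
        side <- (i - 1L) %% 4L + 1L
        if (side == 1L) plantAnn(p, "GO:0000151", "C", FALSE)
        else if (side == 2L) plantAnn(p, "GO:0043130", "F", FALSE)
        else if (side == 3L) {
          partner <- if (length(prot)) sample(prot, 1) else creb1
          plantIa(p, partner, "MI:0220")
        } else {
          pw <- rbind(pw, data.frame(protein = p, pathway = "KEGG:ko04120",
                                     stringsAsFactors = FALSE))
        }
      } else if (mode == "Q5") {
        plantIa(p, tcf7l2, "MI:0914")
        plantAnn(p, "GO:0043433", "P", io)
        plantAnn(p, "GO:0051091", "P", FALSE)
      }
      ledger <- rbind(ledger, data.frame(protein = p,
                                         template = mode,
                                         inferred_only = io,
                                         stringsAsFactors = FALSE))
    }
  }

  ## Q4 pathway anchor must exist even when no plant used it
  pathwayNodes <- c(pwIds, "KEGG:ko04120")

  ## --- assemble the graph through the normal pipeline ---------------------
  allProteins <- c(prot, plants, creb1, tcf7l2)
  seedPlus <- addTerms(seedGraph, pathwayNodes)
  graph <- populateGraph(
    seedPlus, allProteins,
    annotations = ann, interactions = ia, pathways = pw, infos = infos,
    edges = edges, directStatements = direct, name = "synth-kb")

  list(graph = graph, seedGraph = seedPlus,
       records = list(annotations = ann, interactions = ia, pathways = pw,
                      orthology = orth, infos = infos, edges = edges,
                      directStatements = direct),
       ledger = ledger, config = config)
}

## --- file emission ---------------------------------------------------------

gafLines <- function(ann) {
  if (is.null(ann) || !nrow(ann)) return("!gaf-version: 2.1")
  c("!gaf-version: 2.1",
    "!generated by regkb synthetic fixture generator",
    vapply(seq_len(nrow(ann)), function(i) {
      paste(c(curieNamespace(ann$protein[i]), curieLocal(ann$protein[i]),
              curieLocal(ann$protein[i]), "", ann$go_term[i], "SYN:ref",
              ann$evidence_code[i], "", ann$aspect[i], "", "", "protein",
              sub("^NCBITaxon:", "taxon:", ann$taxon[i]), "20260101",
              "SYNKB", "", ""), collapse = "\t")
    }, character(1)))
}

mitabLines <- function(ia) {
  header <- paste0("#ID(s) interactor A\tID(s) interactor B\t",
                   paste(rep("-", 13), collapse = "\t"))
  if (is.null(ia) || !nrow(ia)) return(header)
  c(header, vapply(seq_len(nrow(ia)), function(i) {
    paste(c(paste0("uniprotkb:", curieLocal(ia$participant_a[i])),
            paste0("uniprotkb:", curieLocal(ia$participant_b[i])),
            rep("-", 9),
            sprintf("psi-mi:\"%s\"(synthetic type)",
                    ia$interaction_type[i]),
            "-", ia$interaction_id[i], "-"), collapse = "\t")
  }, character(1)))
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Write a generated knowledge base as a standard-format file bundle
#'
#' Emits the fixture in exactly the formats the readers consume:
#' `ontology.obo`, `annotations.gaf`, `interactions.mitab`,
#' `pathways.tsv`, `orthology.tsv`, `protein_info.tsv`,
#' `regulatory_edges.tsv`, `statements.tsv` (direct sub-relation
#' statements) and `plant_ledger.tsv`. Output is deterministic for a given
#' generator seed.
#'
#' @param kb Result of [generateKB()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeKBFiles <- function(kb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- kb$records
  paths <- c(
    ontology = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.gaf"),
    interactions = file.path(dir, "interactions.mitab"),
    pathways = file.path(dir, "pathways.tsv"),
    orthology = file.path(dir, "orthology.tsv"),
    protein_info = file.path(dir, "protein_info.tsv"),
    regulatory_edges = file.path(dir, "regulatory_edges.tsv"),
    statements = file.path(dir, "statements.tsv"),
    ledger = file.path(dir, "plant_ledger.tsv"))
  serializeOBO(kb$seedGraph, paths["ontology"])
  writeLines(gafLines(rec$annotations), paths["annotations"])
  writeLines(mitabLines(rec$interactions), paths["interactions"])
  empty <- function(cols) stats::setNames(
    as.data.frame(replicate(length(cols), character(), simplify = FALSE),
                  stringsAsFactors = FALSE), cols)
  writeTsv(if (is.null(rec$pathways)) empty(c("protein", "pathway"))
           else rec$pathways, paths["pathways"])
  writeTsv(if (is.null(rec$orthology)) empty(c("protein_a", "protein_b"))
           else rec$orthology, paths["orthology"])
  writeTsv(if (is.null(rec$infos))
             empty(c("accession", "gene", "modified_residues", "taxon"))
           else rec$infos, paths["protein_info"])
  writeTsv(if (is.null(rec$edges))
             empty(c("regulator", "target_gene", "mode", "source_db"))
           else rec$edges, paths["regulatory_edges"])
  writeTsv(if (is.null(rec$directStatements))
             empty(c("subject", "predicate", "object"))
           else rec$directStatements, paths["statements"])
  writeTsv(kb$ledger, paths["ledger"])
  invisible(paths)
}

#' The published shared-target worked example
#'
#' Loads the packaged transcription of the published DbTF/target-gene
#' categorisation table: 20 rows linking five novel DbTFs (CREM, FOXP3,
#' TCF7L2, SMAD3, PARP1) through their regulatory mode to the two core
#' network DbTFs (CREB1, NFkB1) and 19 unique shared target genes, with the
#' model-system expression and responsiveness calls for each target, plus
#' the expression calls for the regulators themselves (CREM, TCF7L2 and
#' PARP1 are expressed).
#'
#' @return A list:
#'   \describe{
#'     \item{`table`}{the transcription as printed (one row per
#'       novel/core/target combination).}
#'     \item{`edges`}{the implied regulatory-edge table (novel and core
#'       edges), suitable for [sharedTargets()].}
#'     \item{`novel`, `core`}{the two regulator sets.}
#'     \item{`targetExpression`}{expression evidence for the target genes.}
#'     \item{`regulatorExpression`}{expression evidence for the novel
#'       regulators.}
#'   }
#' @examples
#' fx <- table2Fixture()
#' rows <- sharedTargets(fx$novel, fx$core, fx$edges)
#' nrow(rows)                        # 20
#' length(unique(rows$target_gene))  # 19
#' @export
table2Fixture <- function() {
  path <- system.file("extdata", "cck2r_shared_targets.tsv",
                      package = "regkb", mustWork = TRUE)
  tab <- readTable(path, c("novel", "mode", "core", "target_gene",
                           "ar42j_expressed", "gastrin_responsive"))
  novelEdges <- unique(data.frame(
    regulator = tab$novel, target_gene = toupper(tab$target_gene),
    mode = tolower(tab$mode), source_db = "curated",
    stringsAsFactors = FALSE))
  coreEdges <- unique(data.frame(
    regulator = tab$core, target_gene = toupper(tab$target_gene),
    mode = "unknown", source_db = "curated", stringsAsFactors = FALSE))
  targetExpression <- unique(data.frame(
    entity = toupper(tab$target_gene),
    expressed = asFlag(tab$ar42j_expressed),
    responsive = asFlag(tab$gastrin_responsive), stringsAsFactors = FALSE))
  regPath <- system.file("extdata", "ar42j_regulator_expression.tsv",
                         package = "regkb", mustWork = TRUE)
  regulatorExpression <- readExpressionEvidence(regPath)
  list(table = tab, edges = rbind(novelEdges, coreEdges),
       novel = unique(tab$novel), core = unique(tab$core),
       targetExpression = targetExpression,
       regulatorExpression = regulatorExpression)
}
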