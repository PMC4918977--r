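#' @include gpml-write.R idmap.R
NULL

#' Configuration of the synthetic-GPML corpus generator
#'
#' The defaults emulate the structure of the curated pathway collection the
#' converter was built for: a corpus dominated by human pathways across
#' about a dozen model organisms, small-to-medium diagrams in which gene
#' products outnumber metabolites, most data nodes carrying a database
#' cross-reference, and sparse interaction wiring.  All weights are
#' overridable; an identical seed and configuration reproduce the corpus
#' byte-for-byte.
#'
#' @param seed integer RNG seed.
#' @param nPathways number of pathways to generate.
#' @param speciesPool data.frame with columns name, taxonUri.
#' @param speciesWeights sampling weights over the pool rows.
#' @param nodesPerPathway integer range (min, max) of data nodes.
#' @param nodeTypeWeights named weights over the GPML data node types.
#' @param xrefProb probability that an annotatable node carries an xref.
#' @param edgeDensity fraction of unordered node pairs wired with an
#'   interaction.
#' @param arrowheadWeights named weights over arrowhead types.
#' @param mappingFanout named weights over the number of unified identifiers
#'   a cross-reference maps to (names "0", "1", ...).
#' @return Configuration list.
#' @export
generatorConfig <- function(
    seed = 1L,
    nPathways = 5L,
    speciesPool = data.frame(
      name = names(.SPECIES_TAXA),
      taxonUri = paste0("http://identifiers.org/taxonomy/",
                        unname(.SPECIES_TAXA)),
      stringsAsFactors = FALSE),
    speciesWeights = c(0.35, 0.15, 0.10, rep(0.04, nrow(speciesPool) - 3L)),
    nodesPerPathway = c(6L, 18L),
    nodeTypeWeights = c(GeneProduct = 0.45, Metabolite = 0.20,
                        Protein = 0.15, Rna = 0.05, Pathway = 0.05,
                        Complex = 0.05, Unknown = 0.05),
    xrefProb = 0.85,
    edgeDensity = 0.06,
    arrowheadWeights = c(Arrow = 0.40, Line = 0.20, TBar = 0.10,
                         MimConversion = 0.15, MimCatalysis = 0.10,
                         MimInhibition = 0.05),
    mappingFanout = c("0" = 0.2, "1" = 0.6, "2" = 0.2)) {
  stopifnot(nPathways >= 0, all(nodeTypeWeights >= 0),
            all(arrowheadWeights >= 0), all(mappingFanout >= 0),
            length(speciesWeights) == nrow(speciesPool))
  list(seed = as.integer(seed), nPathways = as.integer(nPathways),
       speciesPool = speciesPool, speciesWeights = speciesWeights,
       nodesPerPathway = nodesPerPathway,
       nodeTypeWeights = nodeTypeWeights / sum(nodeTypeWeights),
       xrefProb = xrefProb, edgeDensity = edgeDensity,
       arrowheadWeights = arrowheadWeights / sum(arrowheadWeights),
       mappingFanout = mappingFanout / sum(mappingFanout))
}

# xref system choices per node type; accession rendered from a corpus-unique
# integer so no two boxes in the corpus share a subject URI by accident
.xrefSystemsFor <- function(nodeType) {
  switch(nodeType,
         GeneProduct = c("Entrez Gene", "Ensembl"),
         Protein = c("UniProt", "Ensembl"),
         Rna = c("Ensembl", "Entrez Gene"),
         Metabolite = c("ChEBI", "HMDB", "PubChem-compound", "ChemSpider"),
         NULL)
}

.renderAccession <- function(system, serial) {
  switch(system,
         "Entrez Gene" = as.character(100000L + serial),
         "Ensembl" = sprintf("ENSG%011d", serial),
         "UniProt" = sprintf("P%05d", serial %% 100000L),
         "ChEBI" = sprintf("CHEBI:%d", 10000L + serial),
         "HMDB" = sprintf("HMDB%07d", serial),
         "PubChem-compound" = as.character(5000000L + serial),
         "ChemSpider" = as.character(800000L + serial),
         "EntrezGene" = as.character(100000L + serial),
         stop("no accession scheme for system ", system))
}

.unifiedAccession <- function(system, serial) {
  switch(system,
         EntrezGene = as.character(100000L + serial),
         Ensembl = sprintf("ENSG%011d", serial),
         UniProt = sprintf("P%05d", serial %% 100000L),
         HMDB = sprintf("HMDB%07d", serial),
         ChemSpider = as.character(800000L + serial))
}

.sampleWeighted <- function(choices, weights, n = 1L) {
  choices[sample.int(length(choices), n, replace = TRUE, prob = weights)]
}

#' Generate a deterministic synthetic GPML corpus
#'
#' The ground-truth manifest (per-pathway species, node and edge lists,
#' mapping rows) is assembled first and the GPML documents are rendered from
#' it, so the manifest can serve as an independent oracle for everything the
#' conversion pipeline computes.  Every generated pathway passes
#' \code{\link{validatePathway}} with zero violations.
#'
#' @param config as from \code{\link{generatorConfig}}.
#' @param dir optional output directory; when given, writes one
#'   \code{WPnnnn.gpml} per pathway plus \code{mapping.tsv} and
#'   \code{manifest.yaml}.
#' @return List with elements \code{files} (named character vector of GPML
#'   documents), \code{mappingTsv} (character scalar), \code{manifest}
#'   (list), and \code{models} (list of \linkS4class{PathwayModel}).
#' @export
generateCorpus <- function(config = generatorConfig(), dir = NULL) {
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) suppressWarnings(
      rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(config$seed)

  manifest <- list(seed = config$seed, nPathways = config$nPathways,
                   pathways = list())
  mapping <- data.frame(sourceSystem = character(0), sourceId = character(0),
                        unifiedSystem = character(0),
                        unifiedId = character(0), stringsAsFactors = FALSE)
  policy <- unificationPolicy()
  serial <- 0L
  unifiedSerial <- 500000L

  for (p in seq_len(config$nPathways)) {
    wp <- sprintf("WP%d", 1000L + p)
    sp <- sample.int(nrow(config$speciesPool), 1L,
                     prob = config$speciesWeights)
    nNodes <- sample(seq(config$nodesPerPathway[1], config$nodesPerPathway[2]),
                     1L)
    types <- .sampleWeighted(names(config$nodeTypeWeights),
                             config$nodeTypeWeights, nNodes)
    nodes <- data.frame(graphId = sprintf("n%03d", seq_len(nNodes)),
                        type = types,
                        label = character(nNodes),
                        xrefDb = NA_character_, xrefId = NA_character_,
                        stringsAsFactors = FALSE)
    for (i in seq_len(nNodes)) {
      serial <- serial + 1L
      nodes$label[i] <- switch(types[i],
                               GeneProduct = sprintf("GENE%05d", serial),
                               Protein = sprintf("PROT%05d", serial),
                               Rna = sprintf("RNA%05d", serial),
                               Metabolite = sprintf("CPD%05d", serial),
                               Pathway = sprintf("Linked pathway %d", serial),
                               Complex = sprintf("Complex %d", serial),
                               sprintf("Node %d", serial))
      if (types[i] == "Pathway") {
        # link targets drawn without replacement so no two boxes in one
        # diagram share a linked-pathway subject URI
        taken <- as.integer(sub("^WP", "",
                                nodes$xrefId[which(nodes$xrefDb %in%
                                                     "WikiPathways")])) - 1000L
        free <- setdiff(seq_len(config$nPathways), c(p, taken))
        if (length(free)) {
          other <- if (length(free) == 1L) free else sample(free, 1L)
          nodes$xrefDb[i] <- "WikiPathways"
          nodes$xrefId[i] <- sprintf("WP%d", 1000L + other)
        }
      } else {
        systems <- .xrefSystemsFor(types[i])
        if (!is.null(systems) && stats::runif(1) < config$xrefProb) {
          sys <- systems[sample.int(length(systems), 1L)]
          nodes$xrefDb[i] <- sys
          nodes$xrefId[i] <- .renderAccession(sys, serial)
        }
      }
      # unified mapping rows for annotated, routable nodes
      route <- policy$routing[[types[i]]]
      if (!is.na(nodes$xrefDb[i]) && !is.na(route)) {
        fan <- as.integer(.sampleWeighted(names(config$mappingFanout),
                                          config$mappingFanout))
        targets <- names(switch(route, gene = policy$geneTargets,
                                compound = policy$compoundTargets))
        for (j in seq_len(fan)) {
          unifiedSerial <- unifiedSerial + 1L
          tgt <- targets[sample.int(length(targets), 1L)]
          mapping <- rbind(mapping, data.frame(
            sourceSystem = nodes$xrefDb[i], sourceId = nodes$xrefId[i],
            unifiedSystem = tgt,
            unifiedId = .unifiedAccession(tgt, unifiedSerial),
            stringsAsFactors = FALSE))
        }
      }
    }
    # sparse undirected pair sampling, rendered as directed edges
    edges <- data.frame(graphId = character(0), sourceRef = character(0),
                        targetRef = character(0), arrowHead = character(0),
                        stringsAsFactors = FALSE)
    if (nNodes >= 2L && config$edgeDensity > 0) {
      pairs <- utils::combn(nNodes, 2L)
      nEdges <- round(ncol(pairs) * config$edgeDensity)
      if (nEdges > 0L) {
        pick <- sample.int(ncol(pairs), min(nEdges, ncol(pairs)))
        heads <- .sampleWeighted(names(config$arrowheadWeights),
                                 config$arrowheadWeights, length(pick))
        edges <- data.frame(
          graphId = sprintf("e%03d", seq_along(pick)),
          sourceRef = nodes$graphId[pairs[1, pick]],
          targetRef = nodes$graphId[pairs[2, pick]],
          arrowHead = heads, stringsAsFactors = FALSE)
      }
    }
    manifest$pathways[[wp]] <- list(
      wpId = wp, species = config$speciesPool$name[sp],
      taxonUri = config$speciesPool$taxonUri[sp], nodes = nodes,
      edges = edges)
  }
  mapping <- unique(mapping)
  rownames(mapping) <- NULL
  manifest$mapping <- mapping

  models <- lapply(manifest$pathways, .modelFromManifestEntry)
  files <- vapply(models, writeGPML, character(1))
  names(files) <- names(manifest$pathways)
  mappingTsv <- paste0(paste(
    "# synthetic identifier mapping (source_system, source_id, unified_system, unified_id)",
    collapse = "\n"), "\n")
  if (nrow(mapping))
    mappingTsv <- paste0(mappingTsv, paste(
      mapping$sourceSystem, mapping$sourceId, mapping$unifiedSystem,
      mapping$unifiedId, sep = "\t", collapse = "\n"), "\n")

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (wp in names(files))
      writeLines(files[[wp]], file.path(dir, paste0(wp, ".gpml")),
                 useBytes = TRUE)
    writeLines(sub("\n$", "", mappingTsv), file.path(dir, "mapping.tsv"),
               useBytes = TRUE)
    yaml::write_yaml(.manifestToYaml(manifest),
                     file.path(dir, "manifest.yaml"))
  }
  list(files = files, mappingTsv = mappingTsv, manifest = manifest,
       models = models)
}

# grid-render one manifest entry as a PathwayModel
.modelFromManifestEntry <- function(entry) {
  nd <- entry$nodes
  n <- nrow(nd)
  cols <- 6L
  xs <- 160 * ((seq_len(n) - 1L) %% cols) + 80
  ys <- 90 * ((seq_len(n) - 1L) %/% cols) + 45
  nodes <- data.frame(graphId = nd$graphId, textLabel = nd$label,
                      nodeType = nd$type, centerX = xs, centerY = ys,
                      width = 90, height = 25, zOrder = 32768L,
                      xrefDb = nd$xrefDb, xrefId = nd$xrefId,
                      stringsAsFactors = FALSE)
  ed <- entry$edges
  edges <- .emptyEdges()
  for (i in seq_len(nrow(ed))) {
    si <- match(ed$sourceRef[i], nd$graphId)
    ti <- match(ed$targetRef[i], nd$graphId)
    row <- data.frame(graphId = ed$graphId[i], sourceRef = ed$sourceRef[i],
                      targetRef = ed$targetRef[i],
                      arrowHead = ed$arrowHead[i], stringsAsFactors = FALSE)
    row$anchors <- list(character(0))
    row$waypoints <- list(rbind(c(xs[si], ys[si]), c(xs[ti], ys[ti])))
    edges <- rbind(edges, row)
  }
  pathwayModel(wpId = entry$wpId,
               title = sprintf("Synthetic pathway %s", entry$wpId),
               organismName = entry$species,
               organismTaxonUri = entry$taxonUri,
               nodes = nodes, edges = edges,
               sourceFile = paste0(entry$wpId, ".gpml"))
}

.manifestToYaml <- function(manifest) {
  list(seed = manifest$seed, nPathways = manifest$nPathways,
       pathways = lapply(manifest$pathways, function(e) {
         list(wpId = e$wpId, species = e$species, taxonUri = e$taxonUri,
              nodes = lapply(seq_len(nrow(e$nodes)), function(i)
                as.list(e$nodes[i, ])),
              edges = lapply(seq_len(nrow(e$edges)), function(i)
                as.list(e$edges[i, ])))
       }),
       mapping = lapply(seq_len(nrow(manifest$mapping)), function(i)
         as.list(manifest$mapping[i, ])))
}
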