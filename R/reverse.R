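#' @include rules-default.R
NULL

# reverse of the identifiers.org templates: URI -> (system, id); when several
# database spellings share a namespace the canonical GPML spelling wins.
.REVERSE_SYSTEMS <- c("ChEBI", "HMDB", "ChemSpider", "PubChem-compound",
                      "Entrez Gene", "Ensembl", "UniProt", "WikiPathways")

.xrefFromURI <- function(uri, patterns = defaultUriPatterns()) {
  for (sys in .REVERSE_SYSTEMS) {
    base <- sub("$id", "", patterns[[sys]], fixed = TRUE)
    if (startsWith(uri, base))
      return(list(system = sys, id = substring(uri, nchar(base) + 1L)))
  }
  NULL
}

.REVERSE_NODE_CLASS <- c(
  "wp:GeneProduct" = "GeneProduct", "wp:Protein" = "Protein",
  "wp:Rna" = "Rna", "wp:Metabolite" = "Metabolite", "wp:Pathway" = "Pathway",
  "wp:Complex" = "Complex", "wp:DataNode" = "Unknown")

.REVERSE_ARROW_CLASS <- c(
  "wp:DirectedInteraction" = "Arrow", "wp:Inhibition" = "TBar",
  "wp:Conversion" = "MimConversion", "wp:Catalysis" = "MimCatalysis",
  "wp:Interaction" = "Line")

# type guess for untyped members, from their identifiers.org namespace
.typeFromURI <- function(uri) {
  ns <- sub("^http://identifiers.org/([^/]+)/.*$", "\\1", uri)
  switch(ns,
         chebi = , hmdb = , chemspider = , pubchem.compound = "Metabolite",
         ncbigene = , ensembl = "GeneProduct",
         uniprot = "Protein",
         wikipathways = "Pathway",
         "Unknown")
}

#' Reconstruct a pathway model from biological-layer RDF
#'
#' The inverse direction of the conversion: pathway membership
#' (\code{skos:member} / \code{dcterms:isPartOf}) yields data nodes, the
#' biological classes map back to GPML node types (untyped members are
#' classified by their identifiers.org namespace), \code{wp:source} /
#' \code{wp:target} pairs yield interactions, and coordinates are assigned on
#' a deterministic grid so the result renders as a valid diagram.
#'
#' @param wpGraph a \linkS4class{TripleGraph} containing at least one pathway
#'   (a \code{wp:Pathway}-typed subject, or the subject of a
#'   \code{skos:member} statement with a WikiPathways identifiers.org URI).
#' @param layout grid layout defaults: \code{cols}, \code{cellW},
#'   \code{cellH}, \code{nodeW}, \code{nodeH}.
#' @return A \linkS4class{PathwayModel}.
#' @export
reverseToGpml <- function(wpGraph,
                          layout = list(cols = 6L, cellW = 160, cellH = 90,
                                        nodeW = 90, nodeH = 25)) {
  stm <- wpGraph@stm
  typeOf <- function(subj) {
    cls <- stm$object[stm$subject == subj &
                        stm$predicate == uriTerm(.tu("rdf:type"))]
    termFromURI(termValue(cls))
  }
  labelOf <- function(subj) {
    l <- stm$object[stm$subject == subj &
                      stm$predicate == uriTerm(.tu("rdfs:label"))]
    if (length(l)) decodeTerm(sort(l)[1])$value else ""
  }

  pwTyped <- stm$subject[stm$predicate == uriTerm(.tu("rdf:type")) &
                           stm$object == uriTerm(.tu("wp:Pathway"))]
  isPart <- stm$subject[stm$predicate == uriTerm(.tu("dcterms:isPartOf"))]
  candidates <- setdiff(pwTyped, isPart)
  if (!length(candidates)) {
    memberSubj <- stm$subject[stm$predicate == uriTerm(.tu("skos:member"))]
    candidates <- memberSubj[grepl("identifiers.org/wikipathways/",
                                   memberSubj, fixed = TRUE)]
  }
  if (!length(candidates))
    stop("graph contains no pathway subject to reconstruct from")
  pw <- sort(unique(candidates))[1]

  wpIdGuess <- sub("^.*wikipathways/", "", termValue(pw))
  if (!grepl("^WP[0-9]+$", wpIdGuess)) wpIdGuess <- "WP0"
  orgName <- {
    o <- stm$object[stm$subject == pw &
                      stm$predicate == uriTerm(.tu("wp:organismName"))]
    if (length(o)) decodeTerm(o[1])$value else NA_character_
  }
  taxon <- {
    o <- stm$object[stm$subject == pw &
                      stm$predicate == uriTerm(.tu("wp:organism"))]
    if (length(o)) termValue(o[1]) else .taxonURI(orgName)
  }
  title <- {
    o <- stm$object[stm$subject == pw &
                      stm$predicate == uriTerm(.tu("dc:title"))]
    if (length(o)) decodeTerm(o[1])$value else labelOf(pw)
  }

  members <- union(
    stm$object[stm$subject == pw & stm$predicate == uriTerm(.tu("skos:member"))],
    stm$subject[stm$predicate == uriTerm(.tu("dcterms:isPartOf")) &
                  stm$object == pw])
  members <- sort(unique(members[isURITerm(members)]))
  edgeSubjects <- unique(c(
    stm$subject[stm$predicate %in% uriTerm(.tu(c("wp:source", "wp:target",
                                                 "wp:participants")))],
    stm$subject[stm$predicate == uriTerm(.tu("rdf:type")) &
                  stm$object %in%
                    uriTerm(.tu(setdiff(names(.REVERSE_ARROW_CLASS),
                                        "wp:Pathway")))]))
  labelSubjects <- stm$subject[stm$predicate == uriTerm(.tu("rdf:type")) &
                                 stm$object == uriTerm(.tu("wp:Label"))]
  nodeSubjects <- setdiff(members, c(edgeSubjects, labelSubjects, pw))

  grid <- function(k) {
    col <- (k - 1L) %% layout$cols
    row <- (k - 1L) %/% layout$cols
    c(x = layout$cellW * col + layout$cellW / 2,
      y = layout$cellH * row + layout$cellH / 2)
  }

  nodes <- .emptyNodes()
  for (k in seq_along(nodeSubjects)) {
    subj <- nodeSubjects[k]
    uri <- termValue(subj)
    types <- typeOf(subj)
    nodeType <- NA_character_
    for (t in types) {
      if (!is.na(t) && t %in% names(.REVERSE_NODE_CLASS)) {
        nodeType <- .REVERSE_NODE_CLASS[[t]]
        break
      }
    }
    if (is.na(nodeType)) nodeType <- .typeFromURI(uri)
    src <- stm$object[stm$subject == subj &
                        stm$predicate == uriTerm(.tu("dc:source"))]
    accession <- stm$object[stm$subject == subj &
                              stm$predicate == uriTerm(.tu("dcterms:identifier"))]
    if (length(src) && length(accession)) {
      xdb <- decodeTerm(src[1])$value
      xid <- decodeTerm(accession[1])$value
    } else {
      xr <- .xrefFromURI(uri)
      xdb <- if (is.null(xr)) NA_character_ else xr$system
      xid <- if (is.null(xr)) NA_character_ else xr$id
    }
    xy <- grid(k)
    nodes <- rbind(nodes, data.frame(
      graphId = sprintf("n%04d", k), textLabel = labelOf(subj),
      nodeType = nodeType, centerX = xy[["x"]], centerY = xy[["y"]],
      width = layout$nodeW, height = layout$nodeH, zOrder = 32768L,
      xrefDb = xdb, xrefId = xid, stringsAsFactors = FALSE))
  }
  subjToGraphId <- stats::setNames(nodes$graphId, nodeSubjects)

  edges <- .emptyEdges()
  edgeSubjects <- sort(unique(edgeSubjects))
  for (k in seq_along(edgeSubjects)) {
    subj <- edgeSubjects[k]
    types <- typeOf(subj)
    arrow <- "Line"
    for (t in types) {
      if (!is.na(t) && t %in% names(.REVERSE_ARROW_CLASS)) {
        arrow <- .REVERSE_ARROW_CLASS[[t]]
        break
      }
    }
    ref <- function(pred) {
      o <- stm$object[stm$subject == subj & stm$predicate == uriTerm(.tu(pred))]
      if (length(o) && o[1] %in% names(subjToGraphId))
        subjToGraphId[[o[1]]] else NA_character_
    }
    srcId <- ref("wp:source")
    tgtId <- ref("wp:target")
    coord <- function(id, fallback) {
      i <- match(id, nodes$graphId)
      if (is.na(i)) fallback else c(nodes$centerX[i], nodes$centerY[i])
    }
    row <- data.frame(graphId = sprintf("e%04d", k), sourceRef = srcId,
                      targetRef = tgtId, arrowHead = arrow,
                      stringsAsFactors = FALSE)
    row$anchors <- list(character(0))
    row$waypoints <- list(rbind(coord(srcId, c(0, 0)),
                                coord(tgtId, c(layout$cellW, 0))))
    edges <- rbind(edges, row)
  }

  labels <- .emptyLabels()
  labelSubjects <- sort(unique(labelSubjects))
  for (k in seq_along(labelSubjects)) {
    xy <- grid(nrow(nodes) + k)
    labels <- rbind(labels, data.frame(
      graphId = sprintf("l%04d", k), textLabel = labelOf(labelSubjects[k]),
      centerX = xy[["x"]], centerY = xy[["y"]], width = layout$nodeW,
      height = layout$nodeH, stringsAsFactors = FALSE))
  }

  pathwayModel(wpId = wpIdGuess, title = title, organismName = orgName,
               organismTaxonUri = taxon, nodes = nodes, edges = edges,
               labels = labels, sourceFile = "<reverse>")
}
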