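#' @include AllClasses.R
NULL

# NCBI taxonomy ids for the organisms the corpus generator and the curated
# set commonly use; organisms outside this table keep a name but no taxon URI.
.SPECIES_TAXA <- c(
  "Homo sapiens" = 9606, "Mus musculus" = 10090, "Rattus norvegicus" = 10116,
  "Danio rerio" = 7955, "Drosophila melanogaster" = 7227,
  "Caenorhabditis elegans" = 6239, "Saccharomyces cerevisiae" = 4932,
  "Arabidopsis thaliana" = 3702, "Bos taurus" = 9913, "Gallus gallus" = 9031,
  "Canis familiaris" = 9615, "Sus scrofa" = 9823, "Oryza sativa" = 4530)

.taxonURI <- function(organismName) {
  if (is.na(organismName) || !organismName %in% names(.SPECIES_TAXA))
    return(NA_character_)
  paste0("http://identifiers.org/taxonomy/", .SPECIES_TAXA[[organismName]])
}

.DATANODE_TYPES <- c("GeneProduct", "Protein", "Rna", "Metabolite", "Pathway",
                     "Complex", "Unknown")

.emptyNodes <- function() data.frame(
  graphId = character(0), textLabel = character(0), nodeType = character(0),
  centerX = numeric(0), centerY = numeric(0), width = numeric(0),
  height = numeric(0), zOrder = integer(0), xrefDb = character(0),
  xrefId = character(0), stringsAsFactors = FALSE)

.emptyEdges <- function() {
  df <- data.frame(graphId = character(0), sourceRef = character(0),
                   targetRef = character(0), arrowHead = character(0),
                   stringsAsFactors = FALSE)
  df$anchors <- list()
  df$waypoints <- list()
  df
}

.emptyLabels <- function() data.frame(
  graphId = character(0), textLabel = character(0), centerX = numeric(0),
  centerY = numeric(0), width = numeric(0), height = numeric(0),
  stringsAsFactors = FALSE)

#' Construct a PathwayModel programmatically
#'
#' @param wpId WikiPathways accession ("WP" + digits).
#' @param title pathway title.
#' @param organismName organism name or NA.
#' @param organismTaxonUri taxon URI; by default looked up from the organism
#'   name for the common model organisms.
#' @param nodes,edges,labels element tables (see
#'   \linkS4class{PathwayModel}); missing columns of \code{nodes} get the
#'   documented defaults.
#' @param sourceFile provenance string.
#' @param gpmlNamespace XML namespace used when the model is written out.
#' @return A \linkS4class{PathwayModel}.
#' @export
pathwayModel <- function(wpId, title = "", organismName = NA_character_,
                         organismTaxonUri = .taxonURI(organismName),
                         nodes = .emptyNodes(), edges = .emptyEdges(),
                         labels = .emptyLabels(), sourceFile = "<memory>",
                         gpmlNamespace = "http://pathvisio.org/GPML/2013a") {
  if (nrow(nodes)) {
    defaults <- list(nodeType = "Unknown", zOrder = 0L,
                     xrefDb = NA_character_, xrefId = NA_character_)
    for (col in names(defaults))
      if (is.null(nodes[[col]])) nodes[[col]] <- defaults[[col]]
    nodes$zOrder <- as.integer(nodes$zOrder)
  } else nodes <- .emptyNodes()
  if (!nrow(edges)) edges <- .emptyEdges()
  if (!nrow(labels)) labels <- .emptyLabels()
  rownames(nodes) <- rownames(edges) <- rownames(labels) <- NULL
  new("PathwayModel", wpId = wpId, title = title,
      organismName = organismName, organismTaxonUri = organismTaxonUri,
      nodes = nodes, edges = edges, labels = labels,
      sourceFile = sourceFile, gpmlNamespace = gpmlNamespace)
}

.attrOr <- function(node, name, default = NA_character_) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

.numAttr <- function(node, name, default = NA_real_) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else as.numeric(v)
}

#' Parse a GPML document
#'
#' Accepts any GPML namespace whose element structure matches the WikiPathways
#' dialect (the namespace URI is recorded on the model).  Elements without a
#' GraphId receive a deterministic synthesized id \code{"auto-"} plus the
#' zero-padded document-order ordinal, with a warning.  An Xref whose
#' Database or ID attribute is empty is treated as absent (with a warning).
#'
#' @param x file path, raw vector, or character scalar holding GPML XML.
#' @param wpId optional WikiPathways accession.  When NULL it is taken from a
#'   \code{<Attribute Key="WikiPathwaysID">} child of the Pathway element (as
#'   written by \code{\link{writeGPML}}), else from a file name of the form
#'   \code{WPnnn.gpml}, else \code{"WP0"}.
#' @return A \linkS4class{PathwayModel}.
#' @examples
#' m <- parseGPML(paperFixture("glucose_node"))
#' dataNodes(m)
#' @export
parseGPML <- function(x, wpId = NULL) {
  src <- "<memory>"
  if (is.character(x) && length(x) == 1L && !grepl("<", x, fixed = TRUE)) {
    src <- x
    if (!file.exists(x)) stop("no such file: ", x)
  }
  doc <- tryCatch(xml2::read_xml(x),
                  error = function(e) stop("GPML parse error: ",
                                           conditionMessage(e), call. = FALSE))
  root <- xml2::xml_root(doc)
  nsUri <- xml2::xml_ns(doc)
  nsUri <- if ("d1" %in% names(nsUri)) unname(nsUri[["d1"]]) else ""
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(root) != "Pathway")
    stop("not a GPML document: root element is <", xml2::xml_name(root), ">")

  if (is.null(wpId)) {
    attrNode <- xml2::xml_find_first(
      root, "./Attribute[@Key='WikiPathwaysID']")
    if (!inherits(attrNode, "xml_missing")) {
      wpId <- xml2::xml_attr(attrNode, "Value")
    } else if (grepl("(WP[0-9]+)", basename(src))) {
      wpId <- regmatches(basename(src), regexpr("WP[0-9]+", basename(src)))
    } else wpId <- "WP0"
  }

  elements <- xml2::xml_find_all(root, "./DataNode | ./Interaction | ./Label")
  ids <- xml2::xml_attr(elements, "GraphId")
  if (any(is.na(ids))) {
    synth <- sprintf("auto-%04d", which(is.na(ids)))
    warning("synthesized GraphId for ", sum(is.na(ids)),
            " element(s) without one: ", paste(synth, collapse = ", "))
    ids[is.na(ids)] <- synth
  }
  if (anyDuplicated(ids))
    stop("duplicate GraphId in GPML document: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  kind <- xml2::xml_name(elements)

  parseNode <- function(el, id) {
    g <- xml2::xml_find_first(el, "./Graphics")
    xr <- xml2::xml_find_first(el, "./Xref")
    xdb <- xid <- NA_character_
    if (!inherits(xr, "xml_missing")) {
      xdb <- .attrOr(xr, "Database")
      xid <- .attrOr(xr, "ID")
      if (is.na(xdb) || is.na(xid) || !nzchar(xdb) || !nzchar(xid)) {
        warning("node ", id, ": Xref with empty Database or ID treated as absent")
        xdb <- xid <- NA_character_
      }
    }
    tp <- .attrOr(el, "Type", "Unknown")
    if (!tp %in% .DATANODE_TYPES) tp <- "Unknown"
    data.frame(
      graphId = id, textLabel = .attrOr(el, "TextLabel", ""), nodeType = tp,
      centerX = .numAttr(g, "CenterX"), centerY = .numAttr(g, "CenterY"),
      width = .numAttr(g, "Width"), height = .numAttr(g, "Height"),
      zOrder = as.integer(.numAttr(g, "ZOrder", 0)), xrefDb = xdb,
      xrefId = xid, stringsAsFactors = FALSE)
  }

  parseEdge <- function(el, id) {
    g <- xml2::xml_find_first(el, "./Graphics")
    pts <- xml2::xml_find_all(g, "./Point")
    wp <- cbind(x = as.numeric(xml2::xml_attr(pts, "X")),
                y = as.numeric(xml2::xml_attr(pts, "Y")))
    refs <- xml2::xml_attr(pts, "GraphRef")
    heads <- xml2::xml_attr(pts, "ArrowHead")
    arrow <- if (length(heads) && !is.na(heads[length(heads)]))
      heads[length(heads)] else "Line"
    anchors <- xml2::xml_attr(xml2::xml_find_all(g, "./Anchor"), "GraphId")
    anchors <- anchors[!is.na(anchors)]
    df <- data.frame(
      graphId = id,
      sourceRef = if (length(refs)) refs[1] else NA_character_,
      targetRef = if (length(refs) > 1) refs[length(refs)] else NA_character_,
      arrowHead = arrow, stringsAsFactors = FALSE)
    df$anchors <- list(anchors)
    df$waypoints <- list(wp)
    df
  }

  parseLabel <- function(el, id) {
    g <- xml2::xml_find_first(el, "./Graphics")
    data.frame(
      graphId = id, textLabel = .attrOr(el, "TextLabel", ""),
      centerX = .numAttr(g, "CenterX"), centerY = .numAttr(g, "CenterY"),
      width = .numAttr(g, "Width"), height = .numAttr(g, "Height"),
      stringsAsFactors = FALSE)
  }

  nodes <- .emptyNodes(); edges <- .emptyEdges(); labels <- .emptyLabels()
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    row <- switch(kind[i],
                  DataNode = parseNode(el, ids[i]),
                  Interaction = parseEdge(el, ids[i]),
                  Label = parseLabel(el, ids[i]))
    if (kind[i] == "DataNode") nodes <- rbind(nodes, row)
    else if (kind[i] == "Interaction") edges <- rbind(edges, row)
    else labels <- rbind(labels, row)
  }

  orgName <- .attrOr(root, "Organism")
  pathwayModel(wpId = wpId, title = .attrOr(root, "Name", ""),
               organismName = orgName, organismTaxonUri = .taxonURI(orgName),
               nodes = nodes, edges = edges, labels = labels,
               sourceFile = src,
               gpmlNamespace = if (nzchar(nsUri)) nsUri
                               else "http://pathvisio.org/GPML/2013a")
}

#' @rdname wpId
#' @export
setMethod("wpId", "PathwayModel", function(x) x@wpId)

#' @rdname dataNodes
#' @export
setMethod("dataNodes", "PathwayModel", function(x) x@nodes)

#' @rdname interactions
#' @export
setMethod("interactions", "PathwayModel", function(x) x@edges)

#' @rdname freeLabels
#' @export
setMethod("freeLabels", "PathwayModel", function(x) x@labels)

#' @rdname pathwayTitle
#' @export
setMethod("pathwayTitle", "PathwayModel", function(x) x@title)

#' @rdname organism
#' @export
setMethod("organism", "PathwayModel", function(x)
  list(name = x@organismName, taxonUri = x@organismTaxonUri))

setMethod("show", "PathwayModel", function(object) {
  cat(sprintf("PathwayModel %s: \"%s\" (%s)\n", object@wpId, object@title,
              if (is.na(object@organismName)) "organism unknown"
              else object@organismName))
  cat(sprintf("  %d data node(s), %d interaction(s), %d label(s)\n",
              nrow(object@nodes), nrow(object@edges), nrow(object@labels)))
})
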