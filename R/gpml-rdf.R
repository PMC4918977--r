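#' @include idmap.R
NULL

#' Subject URI policy
#'
#' Controls which URI names a pathway element in the RDF output.  The default
#' mode \code{"identifiers_org_when_xref"} gives xref-annotated data nodes
#' their identifiers.org URI (as the published triples do) and everything
#' else a pathway-local URI from the template; \code{"pathway_local_always"}
#' keeps every element pathway-local, which is lossless when one pathway
#' annotates two boxes with the same xref (with the default mode those share
#' a subject and are distinguished by their \code{gpml:graphId} values).
#'
#' @param mode one of \code{"identifiers_org_when_xref"},
#'   \code{"pathway_local_always"}.
#' @param pathwayBase URI template with exactly one \code{\{wp_id\}} and one
#'   \code{\{graph_id\}} slot.
#' @return A policy object (list).
#' @export
subjectUriPolicy <- function(mode = c("identifiers_org_when_xref",
                                      "pathway_local_always"),
                             pathwayBase =
                               "http://rdf.wikipathways.org/{wp_id}/{graph_id}") {
  mode <- match.arg(mode)
  if (lengths(regmatches(pathwayBase, gregexpr("{wp_id}", pathwayBase,
                                               fixed = TRUE))) != 1L ||
      lengths(regmatches(pathwayBase, gregexpr("{graph_id}", pathwayBase,
                                               fixed = TRUE))) != 1L)
    stop("pathwayBase template needs exactly one {wp_id} and one {graph_id}")
  list(mode = mode, pathwayBase = pathwayBase)
}

.pathwayURI <- function(model) {
  mintIdentifiersOrgUri("WikiPathways", model@wpId)
}

.localURI <- function(policy, wpId, graphId) {
  sub("{graph_id}", graphId,
      sub("{wp_id}", wpId, policy$pathwayBase, fixed = TRUE), fixed = TRUE)
}

# Subject URI of data node row i under the policy.
.nodeSubjectURI <- function(model, i, policy, patterns = defaultUriPatterns()) {
  nd <- model@nodes
  if (policy$mode == "identifiers_org_when_xref" && !is.na(nd$xrefDb[i]) &&
      nd$xrefDb[i] %in% names(patterns))
    return(mintIdentifiersOrgUri(nd$xrefDb[i], nd$xrefId[i], patterns))
  .localURI(policy, model@wpId, nd$graphId[i])
}

.pathwayDisplayLabel <- function(model) {
  if (is.na(model@organismName)) model@title
  else sprintf("%s (%s)", model@title, model@organismName)
}

.waypointLiteral <- function(wp) {
  paste(paste(.fmtNum(wp[, 1]), .fmtNum(wp[, 2]), sep = ","), collapse = " ")
}

# Resolve an endpoint reference: list(kind = "element"/"anchor"/NA, uri)
.resolveEndpoint <- function(model, ref, policy, patterns) {
  if (is.na(ref)) return(list(kind = NA_character_, uri = NA_character_))
  nd <- model@nodes
  i <- match(ref, nd$graphId)
  if (!is.na(i))
    return(list(kind = "element",
                uri = .nodeSubjectURI(model, i, policy, patterns)))
  if (ref %in% model@labels$graphId || ref %in% model@edges$graphId)
    return(list(kind = "element", uri = .localURI(policy, model@wpId, ref)))
  owner <- which(vapply(model@edges$anchors, function(a) ref %in% a,
                        logical(1)))
  if (length(owner))
    return(list(kind = "anchor",
                uri = .localURI(policy, model@wpId,
                                model@edges$graphId[owner[1]])))
  list(kind = NA_character_, uri = NA_character_)
}

#' Emit the graphical-layer RDF of a pathway model
#'
#' One-to-one serialization of the GPML content into GPML-vocabulary triples:
#' per data node its class, language-tagged label, graph id, z-order (typed
#' \code{xsd:integer}), geometry (typed \code{xsd:float}), declared node type
#' and containing pathway, plus its xref as data source / accession / minted
#' identifiers.org URI; per interaction its class, arrowhead, ordered
#' waypoint list (one literal), endpoint references and anchors; per free
#' label its class, label and geometry; for the pathway its class, title and
#' (when an organism is set) organism name, taxon URI and display label.
#'
#' @param model a valid \linkS4class{PathwayModel}.
#' @param policy subject URI policy, see \code{\link{subjectUriPolicy}}.
#' @param patterns identifiers.org URI templates.
#' @return A \linkS4class{TripleGraph}.
#' @examples
#' g <- emitGpmlLayer(parseGPML(paperFixture("glucose_node")))
#' tripleObjects(g, "http://identifiers.org/chebi/CHEBI:4167",
#'               "http://vocabularies.wikipathways.org/gpml#ZOrder")
#' @export
emitGpmlLayer <- function(model, policy = subjectUriPolicy(),
                          patterns = defaultUriPatterns()) {
  viol <- validatePathway(model)
  if (nrow(viol))
    stop("model does not validate: ",
         paste(unique(viol$rule), collapse = ", "))
  pw <- .pathwayURI(model)
  stm <- makeStatements(
    pw,
    c(.tu("rdf:type"), .tu("dc:title")),
    c(uriTerm(.tu("gpml:Pathway")), litTerm(model@title)))
  if (!is.na(model@organismName)) {
    stm <- rbind(stm,
      makeStatements(pw, .tu("gpml:organismName"),
                     litTerm(model@organismName)),
      makeStatements(pw, .tu("rdfs:label"),
                     litTerm(.pathwayDisplayLabel(model), lang = "en")))
    if (!is.na(model@organismTaxonUri))
      stm <- rbind(stm, makeStatements(pw, .tu("gpml:organism"),
                                       uriTerm(model@organismTaxonUri)))
  }

  nd <- model@nodes
  for (i in seq_len(nrow(nd))) {
    s <- .nodeSubjectURI(model, i, policy, patterns)
    stm <- rbind(stm, makeStatements(
      s,
      .tu(c("rdf:type", "rdfs:label", "gpml:graphId", "gpml:ZOrder",
            "gpml:centerX", "gpml:centerY", "gpml:width", "gpml:height",
            "gpml:dataNodeType", "gpml:pathway")),
      c(uriTerm(.tu("gpml:DataNode")),
        litTerm(nd$textLabel[i], lang = "en"),
        litTerm(nd$graphId[i]),
        intTerm(nd$zOrder[i]),
        floatTerm(c(nd$centerX[i], nd$centerY[i], nd$width[i], nd$height[i])),
        litTerm(nd$nodeType[i]),
        uriTerm(pw))))
    if (!is.na(nd$xrefDb[i])) {
      stm <- rbind(stm, makeStatements(
        s, .tu(c("gpml:xrefDataSource", "gpml:xrefId")),
        litTerm(c(nd$xrefDb[i], nd$xrefId[i]))))
      if (nd$xrefDb[i] %in% names(patterns))
        stm <- rbind(stm, makeStatements(
          s, .tu("gpml:xrefUri"),
          uriTerm(mintIdentifiersOrgUri(nd$xrefDb[i], nd$xrefId[i],
                                        patterns))))
    }
  }

  ed <- model@edges
  for (i in seq_len(nrow(ed))) {
    s <- .localURI(policy, model@wpId, ed$graphId[i])
    stm <- rbind(stm, makeStatements(
      s,
      .tu(c("rdf:type", "gpml:graphId", "gpml:arrowHead", "gpml:points",
            "gpml:pathway")),
      c(uriTerm(.tu("gpml:Interaction")),
        litTerm(c(ed$graphId[i], ed$arrowHead[i],
                  .waypointLiteral(ed$waypoints[[i]]))),
        uriTerm(pw))))
    src <- .resolveEndpoint(model, ed$sourceRef[i], policy, patterns)
    tgt <- .resolveEndpoint(model, ed$targetRef[i], policy, patterns)
    if (!is.na(src$kind))
      stm <- rbind(stm, makeStatements(
        s, .tu(if (src$kind == "anchor") "gpml:anchorRef"
               else "gpml:sourceRef"), uriTerm(src$uri)))
    if (!is.na(tgt$kind))
      stm <- rbind(stm, makeStatements(
        s, .tu(if (tgt$kind == "anchor") "gpml:anchorRef"
               else "gpml:targetRef"), uriTerm(tgt$uri)))
    for (a in ed$anchors[[i]])
      stm <- rbind(stm, makeStatements(s, .tu("gpml:anchor"), litTerm(a)))
  }

  lb <- model@labels
  for (i in seq_len(nrow(lb))) {
    s <- .localURI(policy, model@wpId, lb$graphId[i])
    stm <- rbind(stm, makeStatements(
      s,
      .tu(c("rdf:type", "rdfs:label", "gpml:graphId", "gpml:centerX",
            "gpml:centerY", "gpml:width", "gpml:height", "gpml:pathway")),
      c(uriTerm(.tu("gpml:Label")),
        litTerm(lb$textLabel[i], lang = "en"),
        litTerm(lb$graphId[i]),
        floatTerm(c(lb$centerX[i], lb$centerY[i], lb$width[i], lb$height[i])),
        uriTerm(pw))))
  }
  graphFromStatements(stm)
}
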