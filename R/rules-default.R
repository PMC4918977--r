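#' @include rules.R
NULL

#' Node-type and arrowhead semantic maps
#'
#' \code{nodeTypeMap} assigns every GPML data node type its biological-layer
#' class; \code{arrowSemanticsMap} assigns every arrowhead its interaction
#' class, with unknown arrowhead strings falling back to the undirected
#' \code{wp:Interaction}.  Both maps are total and overridable when building
#' a custom rule set.
#'
#' @return Named character vector (prefixed class names).
#' @export
nodeTypeMap <- function() {
  c(GeneProduct = "wp:GeneProduct", Protein = "wp:Protein", Rna = "wp:Rna",
    Metabolite = "wp:Metabolite", Pathway = "wp:Pathway",
    Complex = "wp:Complex", Unknown = "wp:DataNode")
}

#' @rdname nodeTypeMap
#' @export
arrowSemanticsMap <- function() {
  c(Arrow = "wp:DirectedInteraction", TBar = "wp:Inhibition",
    MimConversion = "wp:Conversion", MimCatalysis = "wp:Catalysis",
    MimInhibition = "wp:Inhibition", Line = "wp:Interaction")
}

.p <- function(s, p, o) {
  enc <- function(t) {
    if (startsWith(t, "?") || startsWith(t, "<") || startsWith(t, "\"")) t
    else uriTerm(.tu(t))
  }
  c(enc(s), enc(p), enc(o))
}

#' The built-in biological-interpretation rule set
#'
#' Mirrors the shipped declarative rule file: data nodes are typed by
#' \code{\link{nodeTypeMap}} and attached to their pathway
#' (\code{dcterms:isPartOf} and \code{skos:member}); labels and identifier
#' annotations are lifted (\code{rdfs:label}, \code{dc:identifier} with the
#' identifiers.org URI, \code{dcterms:identifier} with the bare accession,
#' \code{dc:source} with the database name); the pathway is typed
#' \code{wp:Pathway} with title, display label, organism and organism name;
#' interactions are typed by \code{\link{arrowSemanticsMap}} with
#' \code{wp:source} / \code{wp:target} for node-bound ends and
#' \code{wp:participants} for ends bound to anchors of other interactions.
#'
#' @return List of \linkS4class{RewriteRule}.
#' @export
defaultRules <- function() {
  rules <- list()
  add <- function(name, patterns, templates, filters = list())
    rules[[length(rules) + 1L]] <<- rewriteRule(name, patterns, templates,
                                                filters)
  for (nt in names(nodeTypeMap())) {
    add(paste0("data-node-", tolower(nt)),
        list(.p("?n", "rdf:type", "gpml:DataNode"),
             .p("?n", "gpml:dataNodeType", litTerm(nt)),
             .p("?n", "gpml:pathway", "?p")),
        list(.p("?n", "rdf:type", nodeTypeMap()[[nt]]),
             .p("?n", "dcterms:isPartOf", "?p"),
             .p("?p", "skos:member", "?n")))
  }
  add("data-node-label",
      list(.p("?n", "rdf:type", "gpml:DataNode"),
           .p("?n", "rdfs:label", "?l")),
      list(.p("?n", "rdfs:label", "?l")))
  add("data-node-identifier",
      list(.p("?n", "rdf:type", "gpml:DataNode"),
           .p("?n", "gpml:xrefUri", "?u")),
      list(.p("?n", "dc:identifier", "?u")))
  add("data-node-identifier-literal",
      list(.p("?n", "rdf:type", "gpml:DataNode"),
           .p("?n", "gpml:xrefId", "?i")),
      list(.p("?n", "dcterms:identifier", "?i")))
  add("data-node-source",
      list(.p("?n", "rdf:type", "gpml:DataNode"),
           .p("?n", "gpml:xrefDataSource", "?s")),
      list(.p("?n", "dc:source", "?s")))
  add("pathway",
      list(.p("?p", "rdf:type", "gpml:Pathway"),
           .p("?p", "dc:title", "?t")),
      list(.p("?p", "rdf:type", "wp:Pathway"),
           .p("?p", "dc:title", "?t")))
  add("pathway-label",
      list(.p("?p", "rdf:type", "gpml:Pathway"),
           .p("?p", "rdfs:label", "?l")),
      list(.p("?p", "rdfs:label", "?l")))
  add("pathway-organism",
      list(.p("?p", "rdf:type", "gpml:Pathway"),
           .p("?p", "gpml:organism", "?o")),
      list(.p("?p", "wp:organism", "?o")))
  add("pathway-organism-name",
      list(.p("?p", "rdf:type", "gpml:Pathway"),
           .p("?p", "gpml:organismName", "?n")),
      list(.p("?p", "wp:organismName", "?n")))
  for (ah in names(arrowSemanticsMap())) {
    add(paste0("interaction-", tolower(ah)),
        list(.p("?i", "rdf:type", "gpml:Interaction"),
             .p("?i", "gpml:arrowHead", litTerm(ah)),
             .p("?i", "gpml:pathway", "?p")),
        list(.p("?i", "rdf:type", arrowSemanticsMap()[[ah]]),
             .p("?i", "dcterms:isPartOf", "?p")))
  }
  add("interaction-other",
      list(.p("?i", "rdf:type", "gpml:Interaction"),
           .p("?i", "gpml:arrowHead", "?ah"),
           .p("?i", "gpml:pathway", "?p")),
      list(.p("?i", "rdf:type", "wp:Interaction"),
           .p("?i", "dcterms:isPartOf", "?p")),
      filters = list(list(type = "in", var = "?ah", negate = TRUE,
                          values = litTerm(names(arrowSemanticsMap())))))
  add("interaction-source",
      list(.p("?i", "rdf:type", "gpml:Interaction"),
           .p("?i", "gpml:sourceRef", "?s")),
      list(.p("?i", "wp:source", "?s")))
  add("interaction-target",
      list(.p("?i", "rdf:type", "gpml:Interaction"),
           .p("?i", "gpml:targetRef", "?t")),
      list(.p("?i", "wp:target", "?t")))
  add("interaction-participants",
      list(.p("?i", "rdf:type", "gpml:Interaction"),
           .p("?i", "gpml:anchorRef", "?j")),
      list(.p("?i", "wp:participants", "?j")))
  add("free-label",
      list(.p("?l", "rdf:type", "gpml:Label"),
           .p("?l", "gpml:pathway", "?p"),
           .p("?l", "rdfs:label", "?t")),
      list(.p("?l", "rdf:type", "wp:Label"),
           .p("?l", "dcterms:isPartOf", "?p"),
           .p("?l", "rdfs:label", "?t")))
  rules
}

#' Procedural biological-layer emitter
#'
#' Computes the biological-layer triples directly from the pathway model,
#' without the pattern engine.  Its output is set-equal to
#' \code{applyRules(emitGpmlLayer(model), defaultRules(), includeInput =
#' FALSE)} on every valid model; the two code paths check each other.
#'
#' @inheritParams emitGpmlLayer
#' @return A \linkS4class{TripleGraph} holding only biological-layer triples.
#' @export
wpLayerFromModel <- function(model, policy = subjectUriPolicy(),
                             patterns = defaultUriPatterns()) {
  pw <- .pathwayURI(model)
  stm <- makeStatements(
    pw, c(.tu("rdf:type"), .tu("dc:title")),
    c(uriTerm(.tu("wp:Pathway")), litTerm(model@title)))
  if (!is.na(model@organismName)) {
    stm <- rbind(stm,
      makeStatements(pw, .tu("wp:organismName"), litTerm(model@organismName)),
      makeStatements(pw, .tu("rdfs:label"),
                     litTerm(.pathwayDisplayLabel(model), lang = "en")))
    if (!is.na(model@organismTaxonUri))
      stm <- rbind(stm, makeStatements(pw, .tu("wp:organism"),
                                       uriTerm(model@organismTaxonUri)))
  }
  ntm <- nodeTypeMap()
  nd <- model@nodes
  for (i in seq_len(nrow(nd))) {
    s <- .nodeSubjectURI(model, i, policy, patterns)
    stm <- rbind(stm,
      makeStatements(s, .tu("rdf:type"), uriTerm(.tu(ntm[[nd$nodeType[i]]]))),
      makeStatements(s, .tu("dcterms:isPartOf"), uriTerm(pw)),
      makeStatements(pw, .tu("skos:member"), uriTerm(s)),
      makeStatements(s, .tu("rdfs:label"),
                     litTerm(nd$textLabel[i], lang = "en")))
    if (!is.na(nd$xrefDb[i])) {
      stm <- rbind(stm,
        makeStatements(s, .tu("dcterms:identifier"), litTerm(nd$xrefId[i])),
        makeStatements(s, .tu("dc:source"), litTerm(nd$xrefDb[i])))
      if (nd$xrefDb[i] %in% names(patterns))
        stm <- rbind(stm, makeStatements(
          s, .tu("dc:identifier"),
          uriTerm(mintIdentifiersOrgUri(nd$xrefDb[i], nd$xrefId[i],
                                        patterns))))
    }
  }
  asm <- arrowSemanticsMap()
  ed <- model@edges
  for (i in seq_len(nrow(ed))) {
    s <- .localURI(policy, model@wpId, ed$graphId[i])
    cls <- if (ed$arrowHead[i] %in% names(asm)) asm[[ed$arrowHead[i]]]
           else "wp:Interaction"
    stm <- rbind(stm,
      makeStatements(s, .tu("rdf:type"), uriTerm(.tu(cls))),
      makeStatements(s, .tu("dcterms:isPartOf"), uriTerm(pw)))
    src <- .resolveEndpoint(model, ed$sourceRef[i], policy, patterns)
    tgt <- .resolveEndpoint(model, ed$targetRef[i], policy, patterns)
    if (!is.na(src$kind))
      stm <- rbind(stm, makeStatements(
        s, .tu(if (src$kind == "anchor") "wp:participants" else "wp:source"),
        uriTerm(src$uri)))
    if (!is.na(tgt$kind))
      stm <- rbind(stm, makeStatements(
        s, .tu(if (tgt$kind == "anchor") "wp:participants" else "wp:target"),
        uriTerm(tgt$uri)))
  }
  lb <- model@labels
  for (i in seq_len(nrow(lb))) {
    s <- .localURI(policy, model@wpId, lb$graphId[i])
    stm <- rbind(stm,
      makeStatements(s, .tu("rdf:type"), uriTerm(.tu("wp:Label"))),
      makeStatements(s, .tu("dcterms:isPartOf"), uriTerm(pw)),
      makeStatements(s, .tu("rdfs:label"),
                     litTerm(lb$textLabel[i], lang = "en")))
  }
  graphFromStatements(stm)
}
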