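# Hand-written pattern specs for the stock queries, used with the naive
# backtracking oracle; deliberately independent of the SPARQL parser.
oracleSpecies <- function(graph) {
  sol <- oracleSolve(graph, list(
    c("?pathway", tu("dc:title"), "?title"),
    c("?pathway", tu("wp:organism"), "?organism"),
    c("?pathway", tu("wp:organismName"), "?label"),
    c("?pathway", tu("rdf:type"), uriTerm(pathwayRDF:::.tu("wp:Pathway")))))
  df <- oracleProject(sol, c("?organism", "?label", "?pathway"))
  if (!nrow(df))
    return(data.frame(organism = character(0), label = character(0),
                      numberOfPathways = character(0)))
  agg <- stats::aggregate(df$pathway,
                          by = list(organism = df$organism,
                                    label = df$label), FUN = length)
  names(agg)[3] <- "numberOfPathways"
  agg$numberOfPathways <- as.character(agg$numberOfPathways)
  unique(agg)
}

oracleWp615 <- function(graph) {
  sol <- oracleSolve(graph, list(
    c("?geneProduct", tu("rdf:type"),
      uriTerm(pathwayRDF:::.tu("wp:GeneProduct"))),
    c("?geneProduct", tu("rdfs:label"), "?label"),
    c("?geneProduct", tu("dcterms:isPartOf"), "?pathway"),
    c("?pathway", tu("rdf:type"), uriTerm(pathwayRDF:::.tu("wp:Pathway")))),
    filters = list(list(type = "regex", var = "?pathway",
                        pattern = "WP615", icase = FALSE)))
  unique(oracleProject(sol, c("?pathway", "?label")))
}

oraclePubchem <- function(graph) {
  sol <- oracleSolve(graph, list(
    c("?concept", tu("dcterms:isPartOf"), "?pathway"),
    c("?concept", tu("dc:source"), litTerm("PubChem-compound")),
    c("?concept", tu("dc:identifier"), "?identifier"),
    c("?pathway", tu("rdf:type"), uriTerm(pathwayRDF:::.tu("wp:Pathway")))))
  unique(oracleProject(sol, c("?identifier", "?pathway")))
}

corpusGraph <- function(corpus, withMapping = FALSE) {
  map <- if (withMapping)
    loadMappingTSV(textConnection(corpus$mappingTsv)) else NULL
  gs <- lapply(names(corpus$files), function(wp) {
    m <- parseGPML(corpus$files[[wp]], wpId = wp)
    g <- applyRules(emitGpmlLayer(m))
    if (!is.null(map))
      g <- graphUnion(g, suppressMessages(emitUnifiedTriples(m, map)))
    g
  })
  do.call(graphUnion, gs)
}

wp615Fixture <- function() {
  nodes <- data.frame(
    graphId = c("g1", "g2", "c1"),
    textLabel = c("KIT", "PDGFRA", "imatinib"),
    nodeType = c("GeneProduct", "GeneProduct", "Metabolite"),
    centerX = c(0, 100, 200), centerY = 0, width = 10, height = 10,
    zOrder = 1:3,
    xrefDb = c("Entrez Gene", "Entrez Gene", "PubChem-compound"),
    xrefId = c("3815", "5156", "5291"), stringsAsFactors = FALSE)
  pathwayModel("WP615", title = "Senescence and Autophagy",
               organismName = "Homo sapiens", nodes = nodes)
}

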