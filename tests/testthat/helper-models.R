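# Model fixtures built in code, plus field-wise model equality.

tinyModel <- function(wpId = "WP9001", organismName = "Homo sapiens") {
  nodes <- data.frame(
    graphId = c("g1", "m1", "p1"),
    textLabel = c("TP53", "ATP", "Linked"),
    nodeType = c("GeneProduct", "Metabolite", "Pathway"),
    centerX = c(100, 200, 300), centerY = c(50, 50, 50),
    width = 90, height = 25, zOrder = c(1L, 2L, 3L),
    xrefDb = c("Entrez Gene", "ChEBI", "WikiPathways"),
    xrefId = c("7157", "CHEBI:15422", "WP111"),
    stringsAsFactors = FALSE)
  edges <- data.frame(graphId = "e1", sourceRef = "g1", targetRef = "m1",
                      arrowHead = "Arrow", stringsAsFactors = FALSE)
  edges$anchors <- list(character(0))
  edges$waypoints <- list(rbind(c(100, 50), c(200, 50)))
  labels <- data.frame(graphId = "t1", textLabel = "a note",
                       centerX = 10, centerY = 10, width = 40, height = 12,
                       stringsAsFactors = FALSE)
  pathwayModel(wpId, title = "Tiny fixture", organismName = organismName,
               nodes = nodes, edges = edges, labels = labels)
}

# random but reproducible models for round-trip properties; labels include
# characters that stress XML and RDF escaping
randomModel <- function(idx) {
  nastyLabels <- c("plain", "with \"quotes\"", "amp & <angle>", "tab\tsep",
                   "back\\slash", "café")
  n <- sample(0:8, 1)
  types <- sample(c("GeneProduct", "Protein", "Rna", "Metabolite",
                    "Pathway", "Complex", "Unknown"), n, replace = TRUE)
  nodes <- if (n) data.frame(
    graphId = sprintf("n%02d", seq_len(n)),
    textLabel = sample(nastyLabels, n, replace = TRUE),
    nodeType = types,
    centerX = round(stats::runif(n, 0, 1000), 2),
    centerY = round(stats::runif(n, 0, 1000), 2),
    width = round(stats::runif(n, 10, 200), 2),
    height = round(stats::runif(n, 5, 60), 2),
    zOrder = sample.int(40000L, n),
    xrefDb = ifelse(stats::runif(n) < 0.6, "Ensembl", NA_character_),
    xrefId = sprintf("ENSG%011d", idx * 1000L + seq_len(n)),
    stringsAsFactors = FALSE) else NULL
  if (!is.null(nodes)) nodes$xrefId[is.na(nodes$xrefDb)] <- NA_character_
  m <- if (n >= 2) sample(0:2, 1) else 0L
  edges <- NULL
  if (m > 0) {
    edges <- data.frame(graphId = sprintf("e%02d", seq_len(m)),
                        sourceRef = sample(nodes$graphId, m, replace = TRUE),
                        targetRef = sample(nodes$graphId, m, replace = TRUE),
                        arrowHead = sample(c("Arrow", "TBar", "Weird",
                                             "MimCatalysis", "Line"), m,
                                           replace = TRUE),
                        stringsAsFactors = FALSE)
    edges$anchors <- replicate(m, character(0), simplify = FALSE)
    edges$waypoints <- replicate(m, {
      k <- sample(2:4, 1)
      cbind(round(stats::runif(k, 0, 1000), 2),
            round(stats::runif(k, 0, 1000), 2))
    }, simplify = FALSE)
  }
  org <- sample(c("Homo sapiens", "Mus musculus", NA_character_), 1)
  pathwayModel(sprintf("WP%d", 8000L + idx),
               title = sprintf("Random pathway %d", idx),
               organismName = org,
               nodes = if (is.null(nodes)) pathwayRDF:::.emptyNodes() else nodes,
               edges = if (is.null(edges)) pathwayRDF:::.emptyEdges() else edges)
}

expect_model_equal <- function(a, b) {
  expect_identical(wpId(a), wpId(b))
  expect_identical(pathwayTitle(a), pathwayTitle(b))
  expect_identical(organism(a), organism(b))
  na <- dataNodes(a); nb <- dataNodes(b)
  expect_identical(na[c("graphId", "textLabel", "nodeType", "xrefDb",
                        "xrefId")],
                   nb[c("graphId", "textLabel", "nodeType", "xrefDb",
                        "xrefId")])
  expect_equal(na[c("centerX", "centerY", "width", "height")],
               nb[c("centerX", "centerY", "width", "height")])
  expect_identical(na$zOrder, nb$zOrder)
  ea <- interactions(a); eb <- interactions(b)
  expect_identical(ea[c("graphId", "sourceRef", "targetRef", "arrowHead")],
                   eb[c("graphId", "sourceRef", "targetRef", "arrowHead")])
  expect_identical(lapply(ea$anchors, as.character),
                   lapply(eb$anchors, as.character))
  expect_equal(lapply(ea$waypoints, function(w) unname(as.matrix(w))),
               lapply(eb$waypoints, function(w) unname(as.matrix(w))))
  la <- freeLabels(a); lb <- freeLabels(b)
  expect_identical(la$graphId, lb$graphId)
  expect_identical(la$textLabel, lb$textLabel)
  expect_equal(la[c("centerX", "centerY", "width", "height")],
               lb[c("centerX", "centerY", "width", "height")])
}
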