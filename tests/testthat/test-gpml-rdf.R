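chebiGlc <- "http://identifiers.org/chebi/CHEBI:4167"

test_that("the glucose node emits the documented graphical-layer triples", {
  g <- emitGpmlLayer(parseGPML(paperFixture("glucose_node")))
  expect_true(containsTriple(g, chebiGlc, pathwayRDF:::.tu("rdf:type"),
                             pathwayRDF:::.tu("gpml:DataNode")))
  expect_true(containsTriple(g, chebiGlc,
                             pathwayRDF:::.tu("rdfs:label"),
                             litTerm("Glucose", lang = "en")))
  expect_true(containsTriple(g, chebiGlc, pathwayRDF:::.tu("gpml:graphId"),
                             litTerm("dba83")))
  expect_true(containsTriple(g, chebiGlc, pathwayRDF:::.tu("gpml:ZOrder"),
                             intTerm(32768L)))
  expect_identical(
    tripleObjects(g, chebiGlc, pathwayRDF:::.tu("gpml:centerX")),
    floatTerm(279.0))
})

test_that("an empty organism-less pathway emits exactly the type and title triples", {
  m <- pathwayModel("WP42", title = "Nothing here")
  g <- emitGpmlLayer(m)
  expect_identical(nTriples(g), 2L)
  pw <- "http://identifiers.org/wikipathways/WP42"
  expect_true(containsTriple(g, pw, pathwayRDF:::.tu("rdf:type"),
                             pathwayRDF:::.tu("gpml:Pathway")))
  expect_identical(tripleObjects(g, pw, pathwayRDF:::.tu("dc:title")),
                   litTerm("Nothing here"))
})

test_that("statement counts follow the per-element counting rule on generated fixtures", {
  corpus <- generateCorpus(generatorConfig(seed = 9, nPathways = 5))
  rdfType <- uriTerm(pathwayRDF:::.tu("rdf:type"))
  dataNodeCls <- uriTerm(pathwayRDF:::.tu("gpml:DataNode"))
  for (wp in names(corpus$files)) {
    m <- parseGPML(corpus$files[[wp]], wpId = wp)
    g <- emitGpmlLayer(m)
    nd <- dataNodes(m)
    # n distinct subjects typed gpml:DataNode (xrefs are corpus-unique)
    typed <- g@stm$subject[g@stm$predicate == rdfType &
                             g@stm$object == dataNodeCls]
    expect_identical(length(unique(typed)), nrow(nd))
    # per-element statement count: pathway 2 (+3 organism), node 10 (+3 xref),
    # edge 5 + bound ends, label 8
    ed <- interactions(m)
    expected <- 2L + 3L +
      sum(10L + 3L * (!is.na(nd$xrefDb))) +
      sum(5L + (!is.na(ed$sourceRef)) + (!is.na(ed$targetRef))) +
      8L * nrow(freeLabels(m))
    expect_identical(nTriples(g), expected)
  }
})

test_that("two nodes sharing an xref share a subject under the default policy but not under pathway_local_always", {
  nodes <- data.frame(
    graphId = c("a", "b"), textLabel = "ATP", nodeType = "Metabolite",
    centerX = c(10, 20), centerY = 10, width = 10, height = 10,
    zOrder = c(1L, 2L), xrefDb = "ChEBI", xrefId = "CHEBI:15422",
    stringsAsFactors = FALSE)
  m <- pathwayModel("WP77", title = "dup", nodes = nodes)
  g <- emitGpmlLayer(m)
  subj <- unique(g@stm$subject[g@stm$predicate ==
                                 uriTerm(pathwayRDF:::.tu("gpml:graphId"))])
  expect_identical(length(subj), 1L)
  expect_setequal(
    termValue(tripleObjects(g, termValue(subj),
                            pathwayRDF:::.tu("gpml:graphId"))),
    c("a", "b"))

  gl <- emitGpmlLayer(m, subjectUriPolicy("pathway_local_always"))
  subj2 <- unique(gl@stm$subject[gl@stm$predicate ==
                                   uriTerm(pathwayRDF:::.tu("gpml:graphId"))])
  expect_identical(length(subj2), 2L)
  expect_true(all(grepl("rdf.wikipathways.org", subj2)))
})

test_that("serialization is deterministic and round-trips through both formats", {
  m <- tinyModel()
  g <- applyRules(emitGpmlLayer(m))
  expect_identical(serializeGraph(g, "ntriples"),
                   serializeGraph(g, "ntriples"))
  expect_identical(serializeGraph(g, "turtle"), serializeGraph(g, "turtle"))
  expect_true(graphEquals(readNTriples(serializeGraph(g, "ntriples")), g))
  expect_true(graphEquals(readTurtle(serializeGraph(g, "turtle")), g))
  expect_identical(serializeGraph(tripleGraph(), "ntriples"), "")
})

test_that("serialized output is valid RDF for an independent conformant parser", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  m <- parseGPML(paperFixture("glucose_node"))
  g <- applyRules(emitGpmlLayer(m))
  ttl <- tempfile(fileext = ".ttl")
  nt <- tempfile(fileext = ".nt")
  writeGraph(g, ttl, "turtle")
  writeGraph(g, nt, "ntriples")
  script <- paste(
    "import sys, rdflib",
    "a = rdflib.Graph(); a.parse(sys.argv[1], format='turtle')",
    "b = rdflib.Graph(); b.parse(sys.argv[2], format='nt')",
    "assert set(a) == set(b), 'turtle and ntriples disagree'",
    "print(len(a))", sep = "\n")
  out <- system2(py, c("-c", shQuote(script), ttl, nt), stdout = TRUE)
  expect_identical(as.integer(out[length(out)]), nTriples(g))
})

test_that("labels with quotes, backslashes and non-ASCII survive serialization", {
  g <- tripleGraph("http://x.org/s", "http://x.org/p",
                   litTerm(c("say \"hi\"", "a\\b", "café", "tab\there"),
                           lang = "en"))
  expect_true(graphEquals(readNTriples(serializeGraph(g, "ntriples")), g))
})

test_that("the graphical layer supports full data node field recovery", {
  # reverse mapping: every DataNode field except document order is present
  m <- tinyModel()
  g <- emitGpmlLayer(m)
  stm <- statements(g)
  nd <- dataNodes(m)[dataNodes(m)$graphId == "m1", ]
  subj <- "http://identifiers.org/chebi/CHEBI:15422"
  get <- function(p) stm$object[stm$subject == subj &
                                  stm$predicate == pathwayRDF:::.tu(p)]
  expect_identical(get("gpml:graphId"), "m1")
  expect_identical(get("rdfs:label"), nd$textLabel)
  expect_identical(get("gpml:dataNodeType"), "Metabolite")
  expect_identical(as.numeric(get("gpml:centerX")), nd$centerX)
  expect_identical(as.integer(get("gpml:ZOrder")), nd$zOrder)
  expect_identical(get("gpml:xrefDataSource"), nd$xrefDb)
  expect_identical(get("gpml:xrefId"), nd$xrefId)
})
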