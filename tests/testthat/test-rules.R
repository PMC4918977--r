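wp534pw <- "http://identifiers.org/wikipathways/WP534"
chebi4167 <- "http://identifiers.org/chebi/CHEBI:4167"

test_that("the glucose pathway yields the skos:member statement of the worked example", {
  g <- applyRules(emitGpmlLayer(parseGPML(paperFixture("glucose_node"))))
  expect_true(containsTriple(g, wp534pw, pathwayRDF:::.tu("skos:member"),
                             chebi4167))
})

test_that("a pathway without interactions yields no source/target triples", {
  m <- pathwayModel("WP5", title = "no edges")
  g <- applyRules(emitGpmlLayer(m), includeInput = FALSE)
  preds <- g@stm$predicate
  expect_false(uriTerm(pathwayRDF:::.tu("wp:source")) %in% preds)
  expect_false(uriTerm(pathwayRDF:::.tu("wp:target")) %in% preds)
})

test_that("fully bound directed edges produce exactly one typed instance with source and target each", {
  corpus <- generateCorpus(generatorConfig(seed = 13, nPathways = 4,
                                           edgeDensity = 0.15))
  for (wp in names(corpus$files)) {
    m <- parseGPML(corpus$files[[wp]], wpId = wp)
    g <- applyRules(emitGpmlLayer(m), includeInput = FALSE)
    stm <- g@stm
    withSource <- stm$subject[stm$predicate ==
                                uriTerm(pathwayRDF:::.tu("wp:source"))]
    withTarget <- stm$subject[stm$predicate ==
                                uriTerm(pathwayRDF:::.tu("wp:target"))]
    bound <- intersect(withSource, withTarget)
    ed <- interactions(m)
    expect_identical(length(bound),
                     sum(!is.na(ed$sourceRef) & !is.na(ed$targetRef)))
  }
})

test_that("arrowheads map to their interaction classes, unknown ones to the undirected class", {
  nodes <- data.frame(graphId = c("a", "b"), textLabel = c("A", "B"),
                      nodeType = "GeneProduct", centerX = c(0, 100),
                      centerY = 0, width = 10, height = 10,
                      zOrder = c(1L, 2L), xrefDb = NA_character_,
                      xrefId = NA_character_, stringsAsFactors = FALSE)
  mk <- function(arrow) {
    edges <- data.frame(graphId = "e1", sourceRef = "a", targetRef = "b",
                        arrowHead = arrow, stringsAsFactors = FALSE)
    edges$anchors <- list(character(0))
    edges$waypoints <- list(rbind(c(0, 0), c(100, 0)))
    m <- pathwayModel("WP6", title = "t", nodes = nodes, edges = edges)
    g <- applyRules(emitGpmlLayer(m), includeInput = FALSE)
    cls <- g@stm$object[g@stm$predicate == uriTerm(pathwayRDF:::.tu("rdf:type")) &
                          grepl("wp#", g@stm$object, fixed = TRUE) &
                          g@stm$subject == uriTerm(
                            "http://rdf.wikipathways.org/WP6/e1")]
    termFromURI(termValue(cls))
  }
  expect_identical(mk("Arrow"), "wp:DirectedInteraction")
  expect_identical(mk("TBar"), "wp:Inhibition")
  expect_identical(mk("MimConversion"), "wp:Conversion")
  expect_identical(mk("MimCatalysis"), "wp:Catalysis")
  expect_identical(mk("MimInhibition"), "wp:Inhibition")
  expect_identical(mk("Line"), "wp:Interaction")
  expect_identical(mk("SomeFutureArrow"), "wp:Interaction")
})

test_that("an edge onto an anchor of another interaction becomes wp:participants", {
  nodes <- data.frame(graphId = c("a", "b", "c"), textLabel = c("A", "B", "C"),
                      nodeType = "GeneProduct", centerX = c(0, 100, 50),
                      centerY = c(0, 0, 50), width = 10, height = 10,
                      zOrder = 1:3, xrefDb = NA_character_,
                      xrefId = NA_character_, stringsAsFactors = FALSE)
  edges <- data.frame(graphId = c("e1", "e2"),
                      sourceRef = c("a", "c"), targetRef = c("b", "anch1"),
                      arrowHead = c("MimConversion", "MimCatalysis"),
                      stringsAsFactors = FALSE)
  edges$anchors <- list(c("anch1"), character(0))
  edges$waypoints <- list(rbind(c(0, 0), c(100, 0)),
                          rbind(c(50, 50), c(50, 0)))
  m <- pathwayModel("WP7", title = "catalysis", nodes = nodes, edges = edges)
  g <- applyRules(emitGpmlLayer(m), includeInput = FALSE)
  expect_true(containsTriple(g, "http://rdf.wikipathways.org/WP7/e2",
                             pathwayRDF:::.tu("wp:participants"),
                             "http://rdf.wikipathways.org/WP7/e1"))
  expect_false(containsTriple(g, "http://rdf.wikipathways.org/WP7/e2",
                              pathwayRDF:::.tu("wp:target")))
})

test_that("rule application is monotone and idempotent", {
  g <- emitGpmlLayer(tinyModel())
  once <- applyRules(g)
  twice <- applyRules(once)
  expect_true(all(pathwayRDF:::.stmKey(g@stm) %in%
                    pathwayRDF:::.stmKey(once@stm)))
  expect_true(graphEquals(once, twice))
})

test_that("the shipped rule file is equivalent to the built-in rules and to the procedural emitter", {
  fileRules <- loadRules(defaultRuleFile())
  corpus <- generateCorpus(generatorConfig(seed = 21, nPathways = 5))
  for (wp in names(corpus$files)) {
    m <- parseGPML(corpus$files[[wp]], wpId = wp)
    g <- emitGpmlLayer(m)
    declFile <- applyRules(g, fileRules, includeInput = FALSE)
    declBuiltin <- applyRules(g, includeInput = FALSE)
    proc <- wpLayerFromModel(m)
    expect_true(graphEquals(declFile, declBuiltin))
    expect_true(graphEquals(declBuiltin, proc))
  }
})

test_that("an empty rule file yields no rules and leaves graphs unchanged", {
  rules <- loadRules("# nothing but comments\n")
  expect_identical(rules, list())
  g <- emitGpmlLayer(tinyModel())
  expect_true(graphEquals(applyRules(g, rules), g))
})

test_that("a rule with an unbound template variable is rejected at load time", {
  txt <- paste("rule broken", "match", "  ?n rdf:type gpml:DataNode .",
               "emit", "  ?n rdfs:label ?unbound .", "end", sep = "\n")
  expect_error(loadRules(txt), "broken.*unbound", ignore.case = TRUE)
})

test_that("SPARQL CONSTRUCT text is accepted as a rule dialect", {
  rq <- system.file("queries", "construct_gpml_to_wp.rq",
                    package = "pathwayRDF")
  rules <- loadRules(rq)
  expect_length(rules, 1L)
  expect_identical(rules[[1]]@name, "interaction-construct")
  g <- emitGpmlLayer(tinyModel())
  out <- applyRules(g, rules, includeInput = FALSE)
  # the single CONSTRUCT covers the Arrow case of the full rule set
  full <- applyRules(g, includeInput = FALSE)
  expect_true(all(pathwayRDF:::.stmKey(out@stm) %in%
                    pathwayRDF:::.stmKey(full@stm)))
  expect_true(containsTriple(out, "http://rdf.wikipathways.org/WP9001/e1",
                             pathwayRDF:::.tu("wp:source")))
})

test_that("biology-level round trip preserves nodes, labels, xrefs and edge semantics", {
  corpus <- generateCorpus(generatorConfig(seed = 31, nPathways = 3,
                                           edgeDensity = 0.12))
  asm <- arrowSemanticsMap()
  semClass <- function(ah) ifelse(ah %in% names(asm), asm[ah],
                                  "wp:Interaction")
  for (wp in names(corpus$files)) {
    m <- parseGPML(corpus$files[[wp]], wpId = wp)
    back <- reverseToGpml(applyRules(emitGpmlLayer(m)))
    expect_identical(wpId(back), wpId(m))
    a <- dataNodes(m); b <- dataNodes(back)
    key <- function(df) sort(paste(df$textLabel, df$nodeType, df$xrefDb,
                                   df$xrefId))
    expect_identical(key(b), key(a))
    ea <- interactions(m); eb <- interactions(back)
    lbl <- function(model, ids) {
      nd <- dataNodes(model)
      nd$textLabel[match(ids, nd$graphId)]
    }
    ekey <- function(model) {
      e <- interactions(model)
      sort(paste(lbl(model, e$sourceRef), lbl(model, e$targetRef),
                 unname(semClass(e$arrowHead))))
    }
    expect_identical(ekey(back), ekey(m))
  }
})

test_that("the two-triple membership example reconstructs a glucose metabolite node", {
  m <- reverseToGpml(paperFixture("wp534_intro"))
  expect_identical(wpId(m), "WP534")
  nd <- dataNodes(m)
  expect_identical(nrow(nd), 1L)
  expect_identical(nd$textLabel, "Glucose")
  expect_identical(nd$nodeType, "Metabolite")
  expect_identical(nd$xrefDb, "ChEBI")
  expect_identical(nd$xrefId, "CHEBI:4167")
  expect_identical(nrow(validatePathway(m)), 0L)
})

test_that("a graph without any pathway subject cannot be reversed", {
  g <- tripleGraph("http://x.org/a", "http://x.org/p", "http://x.org/b")
  expect_error(reverseToGpml(g), "no pathway subject")
})
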