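test_that("mapping TSV rows load, collapse and look up as sets", {
  map <- loadMappingTSV(textConnection(paste(
    "# comment",
    "ChEBI\tCHEBI:4167\tHMDB\tHMDB0000122",
    "ChEBI\tCHEBI:4167\tHMDB\tHMDB0000122",
    "ChEBI\tCHEBI:4167\tChemSpider\t5589",
    sep = "\n")))
  expect_identical(nrow(map@records), 2L)
  hit <- lookupUnified(map, "ChEBI", "CHEBI:4167")
  expect_setequal(paste(hit$unifiedSystem, hit$unifiedId),
                  c("HMDB HMDB0000122", "ChemSpider 5589"))
  expect_identical(nrow(lookupUnified(map, "ChEBI", "CHEBI:999")), 0L)
})

test_that("an empty table yields an empty map and empty lookups", {
  map <- loadMappingTSV(textConnection("# only a comment"))
  expect_identical(nrow(map@records), 0L)
  expect_identical(nrow(lookupUnified(map, "ChEBI", "CHEBI:4167")), 0L)
})

test_that("malformed mapping tables are rejected with a line number", {
  expect_error(loadMappingTSV(textConnection("ChEBI\tCHEBI:1\tHMDB")),
               "line 1.*4 tab-separated")
  expect_error(
    loadMappingTSV(textConnection("ChEBI\tCHEBI:1\tKEGG\tC00031")),
    "unknown unified system")
})

test_that("record count equals the distinct-row count on random tables", {
  set.seed(99)
  n <- 1000L
  rows <- data.frame(
    sourceSystem = sample(c("ChEBI", "Entrez Gene"), n, replace = TRUE),
    sourceId = sprintf("ID%03d", sample.int(300L, n, replace = TRUE)),
    unifiedSystem = sample(c("HMDB", "EntrezGene"), n, replace = TRUE),
    unifiedId = sprintf("U%02d", sample.int(50L, n, replace = TRUE)),
    stringsAsFactors = FALSE)
  tsv <- paste(rows$sourceSystem, rows$sourceId, rows$unifiedSystem,
               rows$unifiedId, sep = "\t", collapse = "\n")
  map <- loadMappingTSV(textConnection(tsv))
  expect_identical(nrow(map@records), nrow(unique(rows)))
})

test_that("identifiers.org URIs mint deterministically and reject unknown systems", {
  expect_identical(mintIdentifiersOrgUri("ChEBI", "CHEBI:4167"),
                   "http://identifiers.org/chebi/CHEBI:4167")
  expect_identical(mintIdentifiersOrgUri("WikiPathways", "WP534"),
                   "http://identifiers.org/wikipathways/WP534")
  expect_error(mintIdentifiersOrgUri("NoSuchDB", "x"), "no identifiers.org")
})

test_that("URI templates load from the shipped YAML config", {
  pat <- loadUriPatterns(system.file("extdata", "uri_patterns.yaml",
                                     package = "pathwayRDF"))
  expect_identical(pat[sort(names(pat))],
                   defaultUriPatterns()[sort(names(defaultUriPatterns()))])
})

test_that("a gene node mapped to one Ensembl id gets exactly one wp:bdbEnsembl triple", {
  nodes <- data.frame(graphId = "g1", textLabel = "KIT",
                      nodeType = "GeneProduct", centerX = 0, centerY = 0,
                      width = 10, height = 10, zOrder = 1L,
                      xrefDb = "ChEBI", xrefId = "CHEBI:0",
                      stringsAsFactors = FALSE)
  # use a non-unified source system so only the mapped row contributes
  nodes$xrefDb <- "Entrez Gene"; nodes$xrefId <- "3815"
  m <- pathwayModel("WP10", title = "t", nodes = nodes)
  map <- loadMappingTSV(textConnection(
    "Entrez Gene\t3815\tEnsembl\tENSG00000157404"))
  g <- emitUnifiedTriples(m, map)
  ens <- g@stm[g@stm$predicate == tu("wp:bdbEnsembl"), ]
  expect_identical(nrow(ens), 1L)
  expect_identical(ens$object,
                   uriTerm("http://identifiers.org/ensembl/ENSG00000157404"))
  # self-mapping: the Entrez Gene xref also yields a bdbEntrezGene triple
  expect_true(containsTriple(g, "http://identifiers.org/ncbigene/3815",
                             pathwayRDF:::.tu("wp:bdbEntrezGene"),
                             "http://identifiers.org/ncbigene/3815"))
})

test_that("an unmapped metabolite gets only the original-identifier triple", {
  nodes <- data.frame(graphId = "m1", textLabel = "glc",
                      nodeType = "Metabolite", centerX = 0, centerY = 0,
                      width = 10, height = 10, zOrder = 1L,
                      xrefDb = "ChEBI", xrefId = "CHEBI:4167",
                      stringsAsFactors = FALSE)
  m <- pathwayModel("WP11", title = "t", nodes = nodes)
  suppressMessages(g <- emitUnifiedTriples(m, identifierMap()))
  expect_identical(nTriples(g), 1L)
  expect_identical(g@stm$predicate, tu("dc:identifier"))
  expect_identical(g@stm$object,
                   uriTerm("http://identifiers.org/chebi/CHEBI:4167"))
})

test_that("gene and compound predicates never cross node classes", {
  corpus <- generateCorpus(generatorConfig(seed = 17, nPathways = 5))
  map <- loadMappingTSV(textConnection(corpus$mappingTsv))
  genePreds <- tu(c("wp:bdbEntrezGene", "wp:bdbEnsembl", "wp:bdbUniprot"))
  compoundPreds <- tu(c("wp:bdbHmdb", "wp:bdbChemspider"))
  for (wp in names(corpus$files)) {
    m <- parseGPML(corpus$files[[wp]], wpId = wp)
    suppressMessages(g <- emitUnifiedTriples(m, map))
    nd <- dataNodes(m)
    policy <- subjectUriPolicy()
    for (i in seq_len(nrow(nd))) {
      if (is.na(nd$xrefDb[i])) next
      subj <- uriTerm(pathwayRDF:::.nodeSubjectURI(m, i, policy))
      preds <- g@stm$predicate[g@stm$subject == subj]
      if (nd$nodeType[i] == "Metabolite")
        expect_false(any(preds %in% genePreds))
      if (nd$nodeType[i] %in% c("GeneProduct", "Protein", "Rna"))
        expect_false(any(preds %in% compoundPreds))
    }
  }
})

test_that("unified triple counts equal the manifest fan-out oracle", {
  corpus <- generateCorpus(generatorConfig(seed = 23, nPathways = 6))
  map <- loadMappingTSV(textConnection(corpus$mappingTsv))
  total <- 0L
  for (wp in names(corpus$files)) {
    m <- parseGPML(corpus$files[[wp]], wpId = wp)
    suppressMessages(g <- emitUnifiedTriples(m, map))
    total <- total + sum(g@stm$predicate %in% bdbPredicates())
  }
  expect_identical(total, manifestBdbCount(corpus$manifest))
})

test_that("identical inputs produce identical unified triple sets", {
  m <- tinyModel()
  map <- loadMappingTSV(textConnection(
    "ChEBI\tCHEBI:15422\tHMDB\tHMDB0000538"))
  g1 <- emitUnifiedTriples(m, map)
  g2 <- emitUnifiedTriples(m, map)
  expect_identical(serializeGraph(g1, "ntriples"),
                   serializeGraph(g2, "ntriples"))
})
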