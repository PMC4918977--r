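# Query-specific oracles shared with the acceptance suite live in
# helper-queries.R.

test_that("the species-count query matches the generator manifest and the join oracle", {
  corpus <- generateCorpus(generatorConfig(seed = 37, nPathways = 8))
  graph <- corpusGraph(corpus)
  res <- runQuery(graph, "species_pathway_counts")
  manifestCounts <- table(vapply(corpus$manifest$pathways,
                                 function(e) e$species, character(1)))
  expect_identical(nrow(res), length(manifestCounts))
  for (i in seq_len(nrow(res)))
    expect_identical(as.integer(res$numberOfPathways[i]),
                     as.integer(manifestCounts[[res$label[i]]]))
  expect_same_rows(res, oracleSpecies(graph))
  # the normalized SPARQL 1.1 variant answers identically
  expect_same_rows(runQuery(graph, "species_pathway_counts_11"), res)
  # ORDER BY DESC: counts never increase down the rows
  expect_false(is.unsorted(rev(as.integer(res$numberOfPathways))))
})

test_that("the WP615 gene-product query returns exactly that pathway's gene products", {
  corpus <- generateCorpus(generatorConfig(seed = 41, nPathways = 3))
  graph <- graphUnion(corpusGraph(corpus),
                      applyRules(emitGpmlLayer(wp615Fixture())))
  res <- runQuery(graph, "gene_products_wp615")
  expect_setequal(res$label, c("KIT", "PDGFRA"))
  expect_identical(unique(res$pathway),
                   "http://identifiers.org/wikipathways/WP615")
  expect_same_rows(res, oracleWp615(graph))
})

test_that("the PubChem query finds annotated compounds via the typed string literal", {
  graph <- applyRules(emitGpmlLayer(wp615Fixture()))
  res <- runQuery(graph, "pubchem_compounds")
  expect_identical(res$identifier,
                   "http://identifiers.org/pubchem.compound/5291")
  expect_same_rows(res, oraclePubchem(graph))
})

test_that("every stock query on an empty graph returns zero rows", {
  g <- tripleGraph()
  for (q in c("species_pathway_counts", "gene_products_wp615",
              "pubchem_compounds"))
    expect_identical(nrow(runQuery(g, q)), 0L)
})

test_that("engine results equal the brute-force join oracle on generated fixtures", {
  for (seed in c(51, 52)) {
    corpus <- generateCorpus(generatorConfig(seed = seed, nPathways = 4))
    graph <- corpusGraph(corpus)
    expect_lte(sum(vapply(corpus$manifest$pathways,
                          function(e) nrow(e$nodes), integer(1))), 200L)
    expect_same_rows(runQuery(graph, "species_pathway_counts"),
                     oracleSpecies(graph))
    expect_same_rows(runQuery(graph, "gene_products_wp615"),
                     oracleWp615(graph))
    expect_same_rows(runQuery(graph, "pubchem_compounds"),
                     oraclePubchem(graph))
  }
})

test_that("the shipped query set is complete and correctly flagged", {
  qs <- storedQueries()
  files <- list.files(system.file("queries", package = "pathwayRDF"),
                      pattern = "\\.rq$")
  expect_identical(length(qs), length(files))
  expect_true(any(vapply(qs, function(q)
    grepl('\\?concept dc:source "PubChem-compound"', q@sparql),
    logical(1))))
  expect_true(qs[["federated_disgenet_asthma"]]@federated)
  expect_match(qs[["federated_disgenet_asthma"]]@sparql,
               'regex\\(\\?diseaseLabel, "asthma", "i"\\)')
  expect_true(any(vapply(qs, function(q)
    grepl("^\\s*CONSTRUCT", q@sparql, ignore.case = TRUE) ||
      grepl("\nCONSTRUCT", q@sparql), logical(1))))
  expect_error(runQuery(tripleGraph(), "federated_atlas_expression"),
               "federated")
  expect_error(runQuery(tripleGraph(), "nosuchquery"), "unknown stored query")
})

test_that("ad hoc SELECT text and stored CONSTRUCT queries execute", {
  g <- applyRules(emitGpmlLayer(tinyModel()))
  res <- runQuery(g, paste(
    "SELECT ?label WHERE {",
    "  ?n rdf:type wp:GeneProduct .",
    "  ?n rdfs:label ?label .",
    "}"))
  expect_identical(res$label, "TP53")
  built <- runQuery(emitGpmlLayer(tinyModel()), "construct_gpml_to_wp")
  expect_s4_class(built, "TripleGraph")
  expect_true(containsTriple(built, "http://rdf.wikipathways.org/WP9001/e1",
                             pathwayRDF:::.tu("wp:source")))
})
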