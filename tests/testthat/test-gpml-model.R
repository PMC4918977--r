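test_that("the printed glucose data node parses to the documented field values", {
  m <- parseGPML(paperFixture("glucose_node"))
  expect_identical(wpId(m), "WP534")
  nd <- dataNodes(m)
  expect_identical(nrow(nd), 1L)
  expect_identical(nd$graphId, "dba83")
  expect_identical(nd$textLabel, "Glucose")
  expect_identical(nd$nodeType, "Metabolite")
  expect_equal(nd$centerX, 279.0)
  expect_equal(nd$centerY, 468.0)
  expect_equal(nd$width, 112.0)
  expect_equal(nd$height, 20.0)
  expect_identical(nd$zOrder, 32768L)
  expect_identical(nd$xrefDb, "ChEBI")
  expect_identical(nd$xrefId, "CHEBI:4167")
  expect_identical(organism(m)$name, "Homo sapiens")
})

test_that("a pathway element without children yields an empty model", {
  m <- parseGPML('<Pathway Name="empty"/>', wpId = "WP1")
  expect_identical(nrow(dataNodes(m)), 0L)
  expect_identical(nrow(interactions(m)), 0L)
  expect_identical(nrow(freeLabels(m)), 0L)
})

test_that("parsed element counts match an independent count over the XML text", {
  set.seed(42)
  corpus <- generateCorpus(generatorConfig(seed = 11, nPathways = 4))
  for (wp in names(corpus$files)) {
    txt <- corpus$files[[wp]]
    m <- parseGPML(txt, wpId = wp)
    expect_identical(nrow(dataNodes(m)), countXmlElements(txt, "DataNode"))
    expect_identical(nrow(interactions(m)),
                     countXmlElements(txt, "Interaction"))
    expect_identical(nrow(freeLabels(m)), countXmlElements(txt, "Label"))
  }
})

test_that("malformed XML reports a parse error with position information", {
  expect_error(parseGPML("<Pathway><DataNode></Pathway>"), "GPML parse error")
})

test_that("a non-Pathway root is rejected", {
  expect_error(parseGPML("<NotAPathway/>"), "root element")
})

test_that("missing GraphId values are synthesized deterministically, duplicates are fatal", {
  gpml <- paste0(
    '<Pathway Name="x">',
    '<DataNode TextLabel="A" Type="Metabolite">',
    '<Graphics CenterX="1.0" CenterY="1.0" Width="10.0" Height="10.0" ZOrder="1"/>',
    "</DataNode>",
    '<DataNode TextLabel="B" GraphId="b1" Type="Metabolite">',
    '<Graphics CenterX="2.0" CenterY="2.0" Width="10.0" Height="10.0" ZOrder="2"/>',
    "</DataNode>",
    "</Pathway>")
  expect_warning(m1 <- parseGPML(gpml, wpId = "WP2"), "synthesized GraphId")
  expect_warning(m2 <- parseGPML(gpml, wpId = "WP2"), "synthesized GraphId")
  expect_identical(dataNodes(m1)$graphId[1], "auto-0001")
  expect_identical(dataNodes(m1)$graphId, dataNodes(m2)$graphId)

  dup <- gsub('GraphId="b1"', 'GraphId="auto-0001"', gpml)
  expect_warning(expect_error(parseGPML(dup, wpId = "WP2"),
                              "duplicate GraphId"))
})

test_that("an Xref with empty Database or ID is treated as absent, with a warning", {
  gpml <- paste0(
    '<Pathway Name="x">',
    '<DataNode TextLabel="A" GraphId="a" Type="Metabolite">',
    '<Graphics CenterX="1.0" CenterY="1.0" Width="10.0" Height="10.0" ZOrder="1"/>',
    '<Xref Database="" ID="CHEBI:1"/>',
    "</DataNode></Pathway>")
  expect_warning(m <- parseGPML(gpml, wpId = "WP3"), "treated as absent")
  expect_true(is.na(dataNodes(m)$xrefDb))
  expect_true(is.na(dataNodes(m)$xrefId))
})

test_that("a node without a Type attribute defaults to Unknown", {
  gpml <- paste0(
    '<Pathway Name="x"><DataNode TextLabel="A" GraphId="a">',
    '<Graphics CenterX="1.0" CenterY="1.0" Width="10.0" Height="10.0" ZOrder="1"/>',
    "</DataNode></Pathway>")
  m <- parseGPML(gpml, wpId = "WP4")
  expect_identical(dataNodes(m)$nodeType, "Unknown")
})

test_that("GPML writing round-trips the glucose fixture and the model invariants", {
  m <- parseGPML(paperFixture("glucose_node"))
  m2 <- parseGPML(writeGPML(m))
  expect_model_equal(m, m2)
})

test_that("parse-write round trip is exact on random models", {
  set.seed(20160623)
  for (idx in 1:30) {
    m <- randomModel(idx)
    m2 <- parseGPML(writeGPML(m))
    expect_model_equal(m, m2)
  }
})

test_that("validation reports duplicate ids, dangling references and bad dimensions", {
  m <- tinyModel()
  expect_identical(nrow(validatePathway(m)), 0L)

  bad <- m
  bad@nodes$graphId[2] <- "g1"
  v <- validatePathway(bad)
  expect_true(any(v$rule == "unique_graph_id" & v$graphId == "g1"))
  expect_match(v$message[v$rule == "unique_graph_id"][1], "2 elements")

  dangle <- m
  dangle@nodes <- dangle@nodes[dangle@nodes$graphId != "m1", ]
  v <- validatePathway(dangle)
  expect_identical(v$rule, "dangling_ref")
  expect_identical(v$graphId, "e1")

  flat <- m
  flat@nodes$width[1] <- 0
  expect_true(any(validatePathway(flat)$rule == "node_dimensions"))

  badId <- m
  badId@wpId <- "P53"
  expect_true(any(validatePathway(badId)$rule == "wp_id_pattern"))
})

test_that("writing an invariant-violating model is refused with the failing rule", {
  m <- tinyModel()
  m@nodes$width[1] <- -5
  expect_error(writeGPML(m), "node_dimensions")
})

test_that("every generated fixture parses with zero validation violations", {
  corpus <- generateCorpus(generatorConfig(seed = 3, nPathways = 6))
  for (wp in names(corpus$files)) {
    m <- parseGPML(corpus$files[[wp]], wpId = wp)
    expect_identical(nrow(validatePathway(m)), 0L)
  }
})
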