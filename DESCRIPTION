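Package: pathwayRDF
Title: Semantic Web Representation of GPML Pathway Diagrams
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts pathway diagrams stored in the Graphical Pathway Markup
    Language (GPML) into RDF in two layered vocabularies: a graphical layer
    mirroring the markup (coordinates, z-order, labels) and a biological layer
    (pathways, typed entities, directed interactions) produced by rule-based
    graph rewriting. Cross-references on data nodes are unified to a small set
    of canonical identifier systems (Entrez Gene, Ensembl, UniProt, HMDB,
    ChemSpider) via a mapping table, identifiers.org URIs are minted for all
    annotated entities, and VoID dataset descriptions with license metadata
    are generated alongside the data. Ships the stock SPARQL queries of the
    WikiPathways endpoint together with a small conformant query engine, a
    deterministic synthetic-GPML corpus generator for testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'terms.R'
    'vocab.R'
    'AllGenerics.R'
    'AllClasses.R'
    'gpml-parse.R'
    'triple-graph.R'
    'idmap.R'
    'gpml-rdf.R'
    'serialize.R'
    'sparql-parse.R'
    'sparql-engine.R'
    'rules.R'
    'rules-default.R'
    'reverse.R'
    'void.R'
    'queries.R'
    'gpml-write.R'
    'generator.R'
    'cli.R'
    'fixtures.R'
    'gpml-validate.R'
    'zzz.R'
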