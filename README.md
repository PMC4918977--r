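# pathwayRDF

Biological pathway diagrams are drawn, curated and exchanged as GPML — the
Graphical Pathway Markup Language — an XML dialect that records both the
picture (boxes, lines, coordinates, z-order) and the biology (which box is a
gene product, which a metabolite, which database accession annotates it).
That is a poor substrate for cross-resource queries: a bioinformatician who
wants "all pathways containing a gene that DisGeNET links to asthma" needs
the pathway content as linked data, not as drawings.

pathwayRDF converts GPML pathways into RDF in two layered vocabularies and
makes the result queryable:

* **gpml layer** (`http://vocabularies.wikipathways.org/gpml#`) — a
  one-to-one rendering of the markup: every data node keeps its label,
  graph id, geometry and z-order, e.g.

  ```
  <http://identifiers.org/chebi/CHEBI:4167> rdf:type gpml:DataNode .
  <http://identifiers.org/chebi/CHEBI:4167> rdfs:label "Glucose"@en .
  <http://identifiers.org/chebi/CHEBI:4167> gpml:graphId "dba83" .
  <http://identifiers.org/chebi/CHEBI:4167> gpml:ZOrder 32768 .
  ```

* **wp layer** (`http://vocabularies.wikipathways.org/wp#`) — the biological
  interpretation, produced from the gpml layer by declarative graph
  rewriting (the same mechanism as a SPARQL CONSTRUCT query): typed entities
  (`wp:Metabolite`, `wp:GeneProduct`, ...), pathway membership
  (`skos:member`, `dcterms:isPartOf`), and typed interactions with
  `wp:source` / `wp:target` derived from lines and arrowheads.

Entity identifiers are unified ahead of query time: every cross-reference is
expanded through a mapping table to a small set of canonical systems —
Entrez Gene (`wp:bdbEntrezGene`), Ensembl (`wp:bdbEnsembl`), UniProt
(`wp:bdbUniprot`) for gene products; HMDB (`wp:bdbHmdb`) and ChemSpider
(`wp:bdbChemspider`) for compounds — stored as deliberately redundant
triples with identifiers.org URIs, so joins against external resources need
no mapping service. Each converted file is accompanied by a VoID dataset
description carrying the Creative Commons Attribution 3.0 license and the
exact triple count.

The package also ships the stock SPARQL queries of the WikiPathways
endpoint together with a small query engine (basic graph patterns, FILTER
regex/IN, DISTINCT, COUNT aggregates, ORDER BY), a deterministic
synthetic-GPML corpus generator with a ground-truth manifest for testing,
and a command line (`convert`, `query`, `generate`, `validate`). The two
federated example queries are shipped as documentation and refused at
execution time — they require remote endpoints.

## Worked example

The canonical glucose node — label "Glucose", graph id `dba83`, type
Metabolite, centered at (279, 468), 112 x 20 units, z-order 32768,
cross-referenced to ChEBI:4167 — inside the glycolysis pathway WP534:

```r
library(pathwayRDF)

model <- parseGPML(paperFixture("glucose_node"))
model
#> PathwayModel WP534: "Glycolysis and Gluconeogenesis" (Homo sapiens)
#>   1 data node(s), 0 interaction(s), 0 label(s)

gpml <- emitGpmlLayer(model)            # graphical layer (18 triples)
wp <- applyRules(gpml, includeInput = FALSE)  # biological layer
cat(serializeGraph(wp, "ntriples"))
```

prints, among the 13 biological-layer statements:

```
<http://identifiers.org/wikipathways/WP534> <http://www.w3.org/2004/02/skos/core#member> <http://identifiers.org/chebi/CHEBI:4167> .
<http://identifiers.org/wikipathways/WP534> <http://www.w3.org/2000/01/rdf-schema#label> "Glycolysis and Gluconeogenesis (Homo sapiens)"@en .
<http://identifiers.org/chebi/CHEBI:4167> <http://www.w3.org/2000/01/rdf-schema#label> "Glucose"@en .
```

— glucose is a member of glycolysis, with both human-readable labels. On a
generated corpus the stock queries run the other direction:

```r
dir <- tempfile()
cmdGenerate(dir, seed = 1, nPathways = 5)      # synthetic GPML + mapping TSV
out <- tempfile()
cmdConvert(dir, out, mappingTsv = file.path(dir, "mapping.tsv"))
cmdQuery(out, "species_pathway_counts")
#> organism	label	numberOfPathways
#> http://identifiers.org/taxonomy/9606	Homo sapiens	2
#> ...
```

The same pipeline is available from a shell via
`inst/scripts/pathwayRDF convert|query|generate|validate`.

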