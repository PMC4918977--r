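---
title: "Converting pathway diagrams to linked data: model and methods"
author: "pathwayRDF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting pathway diagrams to linked data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwayRDF)
```

## The conversion model

GPML stores a pathway as a drawing with biological annotations: data nodes
(boxes) with a label, geometry, a declared type and an optional database
cross-reference; interactions (lines) with waypoints, optional anchors and
an arrowhead; and free text labels. pathwayRDF turns such a document into
RDF in two passes.

**Pass 1 — graphical layer.** `emitGpmlLayer()` serializes the parsed model
one-to-one into the `gpml:` vocabulary. Nothing is interpreted: a data node
becomes a `gpml:DataNode` with `gpml:graphId`, `gpml:ZOrder`,
`gpml:centerX/centerY/width/height`, its declared `gpml:dataNodeType`, its
xref (`gpml:xrefDataSource`, `gpml:xrefId`, and the minted identifiers.org
URI as `gpml:xrefUri`), and a `gpml:pathway` link to the containing pathway.
An interaction keeps its arrowhead string, its ordered waypoint list (one
literal, preserving order, which a statement set could not), and its
resolved endpoint references. The statement count of this layer is a
closed-form function of the model — 2 pathway triples (plus 3 when an
organism is set), 10 per data node (plus 3 per xref), 5 per interaction
plus one per bound end, 8 per label — which the test suite recomputes
independently as a counting oracle.

**Pass 2 — biological layer.** `applyRules()` matches declarative rewrite
rules against the graphical layer and instantiates their templates, exactly
the mechanism of a SPARQL CONSTRUCT query. The default rule set types each
data node by its declared GPML type (`nodeTypeMap()`), attaches it to its
pathway with `dcterms:isPartOf` and `skos:member`, lifts labels and
identifier annotations, types the pathway, and interprets each line through
`arrowSemanticsMap()`: an arrow is a `wp:DirectedInteraction` with
`wp:source` and `wp:target`, a T-bar an inhibition, and so on. Rules match
only the input graph (no rule consumes another's output), so application is
order-independent, monotone and idempotent — properties the test suite
asserts directly.

The same biological layer is implemented twice on purpose: once as the rule
engine executing the shipped rule file, once procedurally from the model
(`wpLayerFromModel()`). The two code paths share no traversal logic and
must produce set-equal graphs on every fixture; this equivalence is the
package's core oracle, because it catches errors in either the rule
semantics or the engine.

## Assumptions and representational choices

* **Subject URIs.** Printed usage puts xref-annotated entities at their
  identifiers.org URI, and the default `subjectUriPolicy()` does the same;
  everything else (interactions, labels, unannotated nodes) lives at
  `http://rdf.wikipathways.org/{wp_id}/{graph_id}`. Consequence, handled
  explicitly: two boxes in one diagram with the same xref share a subject,
  and are then distinguished only by their `gpml:graphId` values. The
  `pathway_local_always` mode avoids the collapse when lossless graphics
  work matters.
* **Identifier predicates.** Both spellings in circulation are emitted so
  that every stock query is answerable: `dc:identifier` carries the
  identifiers.org URI of the curator's original xref, `dcterms:identifier`
  the bare accession, and `dc:source` the database name as an `xsd:string`
  literal. The store normalizes `xsd:string`-typed literals to simple
  literals (the two are the same RDF term), so queries using either
  spelling match.
* **Literal typing.** Coordinates are `xsd:float`, z-order `xsd:integer`
  (it is printed unquoted in the reference listings), labels are
  language-tagged `@en`. Floats are rendered with up to 12 significant
  digits and always a decimal point, so serialization is stable and
  re-parses exactly.
* **Pathway display label.** When an organism is set, the pathway gets
  `rdfs:label "Title (Organism)"@en` in the graphical layer and the rule
  layer copies it. The label is computed at emission because pure pattern
  rewriting cannot concatenate strings; organism-less pathways get exactly
  the type and title triples.
* **Unbound and anchored ends.** A line attached to nothing still produces
  a typed interaction instance with whatever role is bound — curation
  reality, and data loss would be worse. A line ending on an *anchor* of
  another interaction (e.g. catalysis onto a conversion line) is emitted as
  `gpml:anchorRef` to the owning interaction and becomes `wp:participants`
  in the biological layer, keeping the rewrite purely declarative.
* **Arrowhead semantics.** The mapping Arrow→DirectedInteraction,
  TBar→Inhibition, MimConversion→Conversion, MimCatalysis→Catalysis,
  MimInhibition→Inhibition, Line→Interaction is an explicit, overridable
  default; unknown arrowhead strings are preserved verbatim in the
  graphical layer and fall back to the undirected `wp:Interaction` via a
  guarded rule (`filter ?ah not in (...)`).
* **WikiPathways accession.** GPML itself does not carry the WP id; the
  parser takes it from an explicit argument, from a PathVisio-style
  `<Attribute Key="WikiPathwaysID">` child (which `writeGPML()` emits so
  the parse-write round trip is exact), or from a `WPnnn.gpml` file name,
  falling back to `WP0`.
* **Missing graph ids** are synthesized as `auto-` plus the zero-padded
  document-order ordinal — deterministic across runs, because the RDF layer
  needs stable subjects.

## Identifier unification

`emitUnifiedTriples()` expands each xref through a four-column mapping
table to the canonical systems, routed by node class: gene-type nodes
(GeneProduct, Protein, Rna) may receive `wp:bdbEntrezGene`,
`wp:bdbEnsembl`, `wp:bdbUniprot`; metabolites `wp:bdbHmdb`,
`wp:bdbChemspider`; other classes receive none. A node whose xref is
already in a unified system gets a `wp:bdb*` triple to itself, so joins of
the form `?gene wp:bdbEntrezGene ?id` need no special-casing. The
alternative design — query expansion through a live mapping service — is
deliberately not implemented: unified identifiers trade triple redundancy
for self-contained data, which is the right trade for a dataset that does
not host a mapping service. The mapping table is treated as authoritative
as given; no liveness or currency checking is attempted.

## The query engine

`runQuery()` implements the SPARQL subset the stock queries need: basic
graph patterns (with `;`/`,` abbreviations and `a`), `FILTER regex`
(including `str()` and the `"i"` flag), `FILTER ... IN / NOT IN`,
`DISTINCT`, `COUNT` aggregates in both the historic `count(?x) as ?y`
spelling (with implicit grouping over the non-aggregated projection, as the
original endpoint behaved) and standard SPARQL 1.1 `GROUP BY`, plus
`ORDER BY` and `LIMIT`. The species-count query is therefore shipped twice:
verbatim and in a normalized 1.1 form; both must answer identically.
Queries may use the well-known prefixes without declaring them, mirroring
endpoint practice. OPTIONAL, UNION, property paths, subqueries and SERVICE
are out of scope; the federated examples are documentation and are refused
with a pointer to `listQueries()`. On every fixture the engine's solutions
are checked against a naive backtracking join oracle that shares no code
with the merge-based implementation.

Joins evaluate the most selective pattern first (fewest matching
statements); ties break in pattern order. Result rows are a solution
multiset; `DISTINCT` deduplicates after projection, and `ORDER BY` sorts
numerically when every key value parses as a number, lexicographically
otherwise.

## Serialization

N-Triples output is sorted lexicographically, so equal graphs serialize to
identical bytes and corpus conversions diff cleanly. Turtle output uses a
sorted prefix block and one statement per line (no predicate grouping);
that subset is what the bundled reader consumes, and both formats are
cross-checked against an independent conformant parser in the test suite.

## The synthetic corpus generator

`generateCorpus()` emulates the *structure* of a curated pathway
collection: about a dozen model organisms with a human-heavy weighting
(human 0.35, mouse 0.15, rat 0.10, the rest uniform), 6–18 data nodes per
pathway, node types weighted toward gene products (0.45) over metabolites
(0.20), proteins (0.15) and the rest, 85% of annotatable nodes carrying an
xref, sparse wiring (6% of node pairs), and a mapping fan-out of 0–2
unified identifiers per xref (weights 0.2/0.6/0.2). These defaults are
fixed study conditions, not tuning knobs. The ground-truth manifest is
assembled *before* any GPML is rendered, and the documents are rendered
from it, so the manifest is an oracle with no circularity: species counts,
node and edge lists and mapping fan-outs can all be checked against the
pipeline's output.

What the generator does **not** emulate: curation noise (malformed XML,
inconsistent arrowheads, free-floating lines are covered only by targeted
hand-written fixtures), realistic biological wiring (edges are sampled
uniformly over node pairs), groups/complex membership, comments, and
literature references. Passing tests on generated corpora therefore
demonstrate the correctness of the conversion mechanics, not robustness to
every artifact found in decade-old community content.

Accessions are rendered from corpus-unique serials so that no two boxes
accidentally share a subject URI, and linked-pathway targets are drawn
without replacement within a diagram for the same reason — the shared-xref
case is exercised separately by a dedicated fixture.

## Reverse conversion

`reverseToGpml()` reconstructs a drawable model from a biological-layer
graph: members come from `skos:member` / `dcterms:isPartOf`, classes map
back through the inverse of `nodeTypeMap()`, and coordinates are assigned
on a deterministic grid (6 columns, 160x90 cells). Two heuristics make the
direction total on sparse graphs: an untyped member is classified by its
identifiers.org namespace (chebi/hmdb/chemspider/pubchem → Metabolite,
ncbigene/ensembl → GeneProduct, uniprot → Protein), and a missing
`dc:source`/`dcterms:identifier` pair is recovered by inverting the URI
templates. Because the arrowhead map is not injective (TBar and
MimInhibition both mean inhibition), the round trip preserves interaction
*semantics*, not arrowhead spellings; the tests compare edges at the
semantic-class level. Multi-pathway graphs reverse to the lexicographically
first pathway subject.

## Problem sizes and runtime

The default test run uses corpora of 3–8 pathways for unit-level oracles, a
50-pathway corpus for the declarative/procedural equivalence sweep, 100
random models for the parse-write round trip, and a 200-pathway corpus
(run twice) for the end-to-end determinism check; the whole suite completes
in a few minutes on one CPU. These sizes were chosen as the smallest that
exercise every weighted branch of the generator; the pipeline itself is
linear in corpus size and has been run well beyond them.

## Known limitations

* GPML Groups, States, Shapes and Biopax reference elements are not
  modeled; Labels are, because the biological vocabulary captures
  descriptive elements.
* The query engine is a subset; complex analytical SPARQL should be run by
  loading the N-Triples output into a full triple store.
* SKOS alignment links to external ontologies ship as a minimal seed
  (BioPAX Pathway and Conversion, both `skos:closeMatch`) plus a
  user-extensible TSV; no reasoning is performed over them.
* The VoID description covers dataset type, title, license, timestamp,
  triple count and subsets — the fields needed for provenance and reuse —
  not a full template-compliance check.
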