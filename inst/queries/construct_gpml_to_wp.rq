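# rule: interaction-construct
# Graph-pattern rewriting as a SPARQL CONSTRUCT: an interaction described by
# its spatial properties (a line with an arrowhead between two boxes) is
# restated as a directed biological interaction with a source and a target.
PREFIX gpml: <http://vocabularies.wikipathways.org/gpml#>
PREFIX wp: <http://vocabularies.wikipathways.org/wp#>
PREFIX dcterms: <http://purl.org/dc/terms/>
CONSTRUCT {
  ?i rdf:type wp:DirectedInteraction .
  ?i wp:source ?s .
  ?i wp:target ?t .
  ?i dcterms:isPartOf ?p .
}
WHERE {
  ?i rdf:type gpml:Interaction .
  ?i gpml:arrowHead "Arrow" .
  ?i gpml:sourceRef ?s .
  ?i gpml:targetRef ?t .
  ?i gpml:pathway ?p .
}
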