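SELECT DISTINCT ?pathway ?label
WHERE {
 ?geneProduct a wp:GeneProduct .
 ?geneProduct rdfs:label ?label .
 ?geneProduct dcterms:isPartOf ?pathway .
 ?pathway rdf:type wp:Pathway .
 FILTER regex(str(?pathway), "WP615") .
}
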