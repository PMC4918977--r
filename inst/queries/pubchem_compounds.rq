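SELECT DISTINCT ?identifier ?pathway
WHERE {
 ?concept dcterms:isPartOf ?pathway .
 ?concept dc:source "PubChem-compound"^^xsd:string .
 ?concept dc:identifier ?identifier .
 ?pathway rdf:type wp:Pathway
}
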