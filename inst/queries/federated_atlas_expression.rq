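# Federated example: for the genes differentially expressed in asthma (EBI
# Expression Atlas), get the gene products associated to a pathway.
# Documentation only: requires the remote Expression Atlas endpoint.
PREFIX identifiers: <http://identifiers.org/ensembl/>
PREFIX atlas: <http://rdf.ebi.ac.uk/resource/atlas/>
PREFIX atlasterms: <http://rdf.ebi.ac.uk/terms/atlas/>
PREFIX efo: <http://www.ebi.ac.uk/efo/>
SELECT DISTINCT ?wpURL ?pwTitle ?Ensembl ?EntrezGene ?expressionValue ?pvalue
WHERE {
  SERVICE <https://www.ebi.ac.uk/rdf/services/atlas/sparql> {
    ?factor rdf:type efo:EFO_0000270 .
    ?value atlasterms:hasFactorValue ?factor .
    ?value atlasterms:isMeasurementOf ?probe .
    ?value atlasterms:pValue ?pvalue .
    ?value rdfs:label ?expressionValue .
    ?probe atlasterms:dbXref ?dbXref .
  }
  ?pwElement dcterms:isPartOf ?pathway .
  ?pathway dc:title ?pwTitle .
  ?pathway dc:identifier ?wpURL .
  ?pwElement wp:bdbEnsembl ?Ensembl .
  ?pwElement wp:bdbEntrezGene ?EntrezGene .
}
ORDER BY ASC(?pvalue)
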