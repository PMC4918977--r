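SELECT DISTINCT ?organism ?label (COUNT(?pathway) AS ?numberOfPathways)
WHERE {
  ?pathway dc:title ?title .
  ?pathway wp:organism ?organism .
  ?pathway wp:organismName ?label .
  ?pathway rdf:type wp:Pathway .
}
GROUP BY ?organism ?label
ORDER BY DESC(?numberOfPathways)
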