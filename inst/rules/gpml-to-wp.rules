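# Default graphical-layer -> biological-layer rewrite rules.
#
# Syntax: "rule <name>" opens a rule; a "match" section lists conjunctive
# triple patterns over the graphical layer, an optional "filter" guards
# bound values, an "emit" section lists the produced triple templates, and
# "end" closes the rule.  Terms are written as prefixed names (the standard
# prefix set is predeclared), <full URIs>, "string literals" or ?variables.

# --- data nodes: biological class, pathway membership -----------------------

rule data-node-geneproduct
match
  ?n rdf:type gpml:DataNode .
  ?n gpml:dataNodeType "GeneProduct" .
  ?n gpml:pathway ?p .
emit
  ?n rdf:type wp:GeneProduct .
  ?n dcterms:isPartOf ?p .
  ?p skos:member ?n .
end

rule data-node-protein
match
  ?n rdf:type gpml:DataNode .
  ?n gpml:dataNodeType "Protein" .
  ?n gpml:pathway ?p .
emit
  ?n rdf:type wp:Protein .
  ?n dcterms:isPartOf ?p .
  ?p skos:member ?n .
end

rule data-node-rna
match
  ?n rdf:type gpml:DataNode .
  ?n gpml:dataNodeType "Rna" .
  ?n gpml:pathway ?p .
emit
  ?n rdf:type wp:Rna .
  ?n dcterms:isPartOf ?p .
  ?p skos:member ?n .
end

rule data-node-metabolite
match
  ?n rdf:type gpml:DataNode .
  ?n gpml:dataNodeType "Metabolite" .
  ?n gpml:pathway ?p .
emit
  ?n rdf:type wp:Metabolite .
  ?n dcterms:isPartOf ?p .
  ?p skos:member ?n .
end

rule data-node-pathway
match
  ?n rdf:type gpml:DataNode .
  ?n gpml:dataNodeType "Pathway" .
  ?n gpml:pathway ?p .
emit
  ?n rdf:type wp:Pathway .
  ?n dcterms:isPartOf ?p .
  ?p skos:member ?n .
end

rule data-node-complex
match
  ?n rdf:type gpml:DataNode .
  ?n gpml:dataNodeType "Complex" .
  ?n gpml:pathway ?p .
emit
  ?n rdf:type wp:Complex .
  ?n dcterms:isPartOf ?p .
  ?p skos:member ?n .
end

rule data-node-unknown
match
  ?n rdf:type gpml:DataNode .
  ?n gpml:dataNodeType "Unknown" .
  ?n gpml:pathway ?p .
emit
  ?n rdf:type wp:DataNode .
  ?n dcterms:isPartOf ?p .
  ?p skos:member ?n .
end

# --- data nodes: labels and identifiers -------------------------------------

rule data-node-label
match
  ?n rdf:type gpml:DataNode .
  ?n rdfs:label ?l .
emit
  ?n rdfs:label ?l .
end

rule data-node-identifier
match
  ?n rdf:type gpml:DataNode .
  ?n gpml:xrefUri ?u .
emit
  ?n dc:identifier ?u .
end

rule data-node-identifier-literal
match
  ?n rdf:type gpml:DataNode .
  ?n gpml:xrefId ?i .
emit
  ?n dcterms:identifier ?i .
end

rule data-node-source
match
  ?n rdf:type gpml:DataNode .
  ?n gpml:xrefDataSource ?s .
emit
  ?n dc:source ?s .
end

# --- pathway-level statements ------------------------------------------------

rule pathway
match
  ?p rdf:type gpml:Pathway .
  ?p dc:title ?t .
emit
  ?p rdf:type wp:Pathway .
  ?p dc:title ?t .
end

rule pathway-label
match
  ?p rdf:type gpml:Pathway .
  ?p rdfs:label ?l .
emit
  ?p rdfs:label ?l .
end

rule pathway-organism
match
  ?p rdf:type gpml:Pathway .
  ?p gpml:organism ?o .
emit
  ?p wp:organism ?o .
end

rule pathway-organism-name
match
  ?p rdf:type gpml:Pathway .
  ?p gpml:organismName ?n .
emit
  ?p wp:organismName ?n .
end

# --- interactions: a line plus an arrowhead becomes a typed interaction -----

rule interaction-arrow
match
  ?i rdf:type gpml:Interaction .
  ?i gpml:arrowHead "Arrow" .
  ?i gpml:pathway ?p .
emit
  ?i rdf:type wp:DirectedInteraction .
  ?i dcterms:isPartOf ?p .
end

rule interaction-tbar
match
  ?i rdf:type gpml:Interaction .
  ?i gpml:arrowHead "TBar" .
  ?i gpml:pathway ?p .
emit
  ?i rdf:type wp:Inhibition .
  ?i dcterms:isPartOf ?p .
end

rule interaction-mimconversion
match
  ?i rdf:type gpml:Interaction .
  ?i gpml:arrowHead "MimConversion" .
  ?i gpml:pathway ?p .
emit
  ?i rdf:type wp:Conversion .
  ?i dcterms:isPartOf ?p .
end

rule interaction-mimcatalysis
match
  ?i rdf:type gpml:Interaction .
  ?i gpml:arrowHead "MimCatalysis" .
  ?i gpml:pathway ?p .
emit
  ?i rdf:type wp:Catalysis .
  ?i dcterms:isPartOf ?p .
end

rule interaction-miminhibition
match
  ?i rdf:type gpml:Interaction .
  ?i gpml:arrowHead "MimInhibition" .
  ?i gpml:pathway ?p .
emit
  ?i rdf:type wp:Inhibition .
  ?i dcterms:isPartOf ?p .
end

rule interaction-line
match
  ?i rdf:type gpml:Interaction .
  ?i gpml:arrowHead "Line" .
  ?i gpml:pathway ?p .
emit
  ?i rdf:type wp:Interaction .
  ?i dcterms:isPartOf ?p .
end

# unknown arrowhead strings fall back to the undirected interaction class
rule interaction-other
match
  ?i rdf:type gpml:Interaction .
  ?i gpml:arrowHead ?ah .
  ?i gpml:pathway ?p .
filter ?ah not in ("Arrow", "TBar", "MimConversion", "MimCatalysis", "MimInhibition", "Line")
emit
  ?i rdf:type wp:Interaction .
  ?i dcterms:isPartOf ?p .
end

rule interaction-source
match
  ?i rdf:type gpml:Interaction .
  ?i gpml:sourceRef ?s .
emit
  ?i wp:source ?s .
end

rule interaction-target
match
  ?i rdf:type gpml:Interaction .
  ?i gpml:targetRef ?t .
emit
  ?i wp:target ?t .
end

# an end bound to an anchor of another interaction participates in it
rule interaction-participants
match
  ?i rdf:type gpml:Interaction .
  ?i gpml:anchorRef ?j .
emit
  ?i wp:participants ?j .
end

# --- free text labels --------------------------------------------------------

rule free-label
match
  ?l rdf:type gpml:Label .
  ?l gpml:pathway ?p .
  ?l rdfs:label ?t .
emit
  ?l rdf:type wp:Label .
  ?l dcterms:isPartOf ?p .
  ?l rdfs:label ?t .
end
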