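# Registry of the shipped stock queries.
- name: species_pathway_counts
  file: species_pathway_counts.rq
  description: List the species captured in the collection and the number of pathways per species
  federated: false
  schema: [organism, label, numberOfPathways]
- name: species_pathway_counts_11
  file: species_pathway_counts_11.rq
  description: Species/pathway counts, normalized SPARQL 1.1 aggregate form
  federated: false
  schema: [organism, label, numberOfPathways]
- name: gene_products_wp615
  file: gene_products_wp615.rq
  description: Get all gene products on a particular pathway (WP615 as an example)
  federated: false
  schema: [pathway, label]
- name: pubchem_compounds
  file: pubchem_compounds.rq
  description: Return all PubChem compounds and the pathways they are in
  federated: false
  schema: [identifier, pathway]
- name: federated_disgenet_asthma
  file: federated_disgenet_asthma.rq
  description: DisGeNET disease-gene pairs on asthma joined to pathway membership
  federated: true
  schema: [wpId, pwtitle, wpgenes]
- name: federated_atlas_expression
  file: federated_atlas_expression.rq
  description: Expression Atlas differential expression joined to pathway gene products
  federated: true
  schema: [wpURL, pwTitle, Ensembl, EntrezGene, expressionValue, pvalue]
- name: construct_gpml_to_wp
  file: construct_gpml_to_wp.rq
  description: CONSTRUCT rule translating a graphical-layer interaction into its biological interpretation
  federated: false
  schema: []
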