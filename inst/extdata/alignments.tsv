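wp_term	external_uri	relation
wp:Pathway	http://www.biopax.org/release/biopax-level3.owl#Pathway	closeMatch
wp:DirectedInteraction	http://www.biopax.org/release/biopax-level3.owl#Conversion	closeMatch
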